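test_that("slice-profile kernel is normalized, symmetric, delta-safe", {
  for (fwhm in c(0.2, 1, 4)) {
    k <- slice_profile_kernel(fwhm, 0.1)
    expect_equal(sum(k), 1, tolerance = 1e-12)
    expect_equal(k, rev(k))
  }
  expect_warning(slice_profile_kernel(0.04, 0.1), "delta")
  expect_error(slice_profile_kernel(0, 0.1), "> 0")
})

test_that("kernel half-maximum sits at half the FWHM", {
  sp <- 1
  k <- slice_profile_kernel(4 * sp, sp)
  x <- seq_along(k) - (length(k) + 1) / 2
  # interpolated crossing of half maximum on the positive side
  xs <- seq(0, max(x), by = 0.001)
  ks <- approx(x, k, xs)$y
  crossing <- xs[which(ks <= max(k) / 2)[1]]
  expect_lt(abs(crossing - 2), 0.5)
})

test_that("constant volumes pass through the forward model unchanged", {
  v <- srr_volume(array(42, c(12, 12, 12)), 1, meta = list(background = 42))
  st <- simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                          acquisition_model(1, 3))
  expect_equal(max(abs(st$data - 42)), 0, tolerance = 1e-12)
})

test_that("a point source reproduces the decimated slice-profile kernel", {
  n <- 31
  v <- srr_volume(array(0, c(n, n, n)), 1, meta = list(background = 0))
  mid <- (n + 1) / 2
  v$data[mid, mid, mid] <- 1
  model <- acquisition_model(1, 3)
  st <- simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0), model)
  kern <- slice_profile_kernel(3, 1)
  hw <- (length(kern) - 1) / 2
  kfun <- function(z) {  # linear interpolation of the discretized kernel
    approx(-hw:hw, kern, z, yleft = 0, yright = 0)$y
  }
  # slice j center in voxel units relative to the bright voxel
  zq <- (st$slice_positions - st$frame_origin[3]) / 1 + 1 - mid
  expect_equal(st$data[mid, mid, ], kfun(zq), tolerance = 1e-9)
  # off-axis inplane voxels stay dark (no inplane blur)
  expect_true(all(st$data[mid + 1, , ] == 0))
})

test_that("AR 1 with a delta profile is the identity", {
  v <- gaussian_blob(12)
  st <- suppressWarnings(
    simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                      acquisition_model(1, 1, blur_fwhm = 1e-6))
  )
  expect_equal(st$data, v$data, tolerance = 1e-12)
  up <- upsample_stack(st)
  expect_equal(up$data, v$data, tolerance = 1e-12)
})

test_that("upsampling interpolates linearly and clamps beyond end slices", {
  v <- srr_volume(array(0, c(4, 4, 8)), 1, meta = list(background = 0))
  ramp <- rep(seq_len(8), each = 16)
  v$data <- array(ramp, c(4, 4, 8))
  st <- suppressWarnings(
    simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                      acquisition_model(1, 2, blur_fwhm = 1e-6))
  )
  up <- upsample_stack(st)
  # interior of a linear ramp is reproduced exactly
  expect_equal(up$data[1, 1, 2:7], as.numeric(2:7), tolerance = 1e-12)
  # beyond the terminal slice centers values clamp to the nearest slice
  expect_equal(up$data[1, 1, 1], st$data[1, 1, 1])
  expect_equal(up$data[1, 1, 8], st$data[1, 1, dim(st$data)[3]])
})

test_that("two-slice stack interpolates the midpoint", {
  v <- srr_volume(array(0, c(4, 4, 4)), 1, meta = list(background = 0))
  v$data[, , 3:4] <- 10
  st <- suppressWarnings(
    simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0),
                      acquisition_model(1, 2, blur_fwhm = 1e-6))
  )
  expect_equal(dim(st$data)[3], 2L)
  up <- upsample_stack(st)
  # midway between slice centers (slices at z index 1.5 and 3.5)
  mid <- (up$data[1, 1, 2] + up$data[1, 1, 3]) / 2
  expect_equal(mid, 5, tolerance = 1e-12)
})

test_that("noiseless stacks conserve mean intensity of the blurred volume", {
  v <- gaussian_blob(24, width = 30)
  model <- acquisition_model(1, 4)
  st <- simulate_lr_stack(v, list(kind = "shifted", shift_mm = 0), model)
  kern <- slice_profile_kernel(4, 1)
  blurred <- array(srrgeom:::cpp_convolve_z(v$data, dim(v$data), kern),
                   dim(v$data))
  zq <- (st$slice_positions - st$frame_origin[3]) / 1 + 1
  ref <- srrgeom:::sample_axis3(blurred, zq)
  expect_equal(mean(st$data), mean(ref), tolerance = 1e-9)
})

test_that("stack noise is seeded and geometry metadata is coherent", {
  v <- gaussian_blob(12)
  model <- acquisition_model(1, 3, noise_sigma = 2)
  g <- list(kind = "shifted", shift_mm = 0)
  a <- simulate_lr_stack(v, g, model, seed = 5)
  b <- simulate_lr_stack(v, g, model, seed = 5)
  c <- simulate_lr_stack(v, g, model, seed = 6)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
  expect_equal(diff(a$slice_positions),
               rep(3, length(a$slice_positions) - 1))
})
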