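test_that("default resolution phantom has five resolved dark tubes", {
  ph <- make_resolution_phantom()
  expect_equal(max(ph$data), 100)
  expect_equal(min(ph$data), 0)
  pr <- ph$meta$tube_profile
  prof <- extract_line_profile(ph, pr$start, pr$end, 513)
  expect_gt(tube_modulation(prof, 5), 0.9)
})

test_that("zero tubes gives a uniform bath", {
  ph <- make_resolution_phantom(grid_shape = 16, n_tubes = 0)
  expect_true(all(ph$data == 100))
})

test_that("void volume matches the analytic cylinder volume on a fine grid", {
  # single tube, spacing = OD/20, tube crosses the whole volume
  od <- 0.7
  sp <- od / 20
  gs <- c(32, 16, 32)
  ph <- make_resolution_phantom(grid_shape = gs, spacing = sp, n_tubes = 1)
  void_frac <- mean((100 - ph$data) / 100)
  analytic <- pi * (od / 2)^2 / (gs[1] * sp * gs[3] * sp)
  expect_equal(void_frac, analytic, tolerance = 0.02)
})

test_that("oblique orientation preserves total void volume", {
  gs <- 64
  sp <- 16 / 64
  # finite tubes fully inside the volume in both orientations (infinite
  # tubes clip against the cube with direction-dependent chord lengths)
  aligned <- make_resolution_phantom(grid_shape = gs, spacing = sp,
                                     tube_length = 8)
  oblique <- make_resolution_phantom(grid_shape = gs, spacing = sp,
                                     tube_length = 8,
                                     orientation = c(40, 55))
  v1 <- sum(100 - aligned$data)
  v2 <- sum(100 - oblique$data)
  expect_equal(v2 / v1, 1, tolerance = 0.03)
})

test_that("tubes outside the field of view name the offending tube", {
  expect_error(
    make_resolution_phantom(grid_shape = 24, spacing = 0.1),
    "tube 1 exceeds"
  )
})

test_that("biological phantom is bit-reproducible per seed, distinct across seeds", {
  a <- make_biological_phantom(grid_shape = 96, seed = 1)
  b <- make_biological_phantom(grid_shape = 96, seed = 1)
  c <- make_biological_phantom(grid_shape = 96, seed = 2)
  expect_identical(a$data, b$data)
  expect_false(identical(a$data, c$data))
})

test_that("biological phantom hosts homogeneous regions and stays in range", {
  ph <- make_biological_phantom(grid_shape = 96, seed = 3)
  r <- ph$meta$rois
  roi <- function(nm) {
    x <- r[r$name == nm, ]
    box_roi(x$corner[[1]], x$size[[1]])
  }
  hi <- as.numeric(roi_values(ph, roi("high")))
  lo <- as.numeric(roi_values(ph, roi("low")))
  contrast <- abs(mean(hi) - mean(lo))
  expect_gt(contrast, 10)
  expect_lt(sd(hi), 0.01 * contrast)
  expect_lt(sd(lo), 0.01 * contrast)
  rng <- ph$meta$intensity_range
  expect_true(all(ph$data >= rng[1] & ph$data <= rng[2]))
  # noise ROI sits in pure background
  bgv <- as.numeric(roi_values(ph, roi("noise")))
  expect_true(all(bgv == ph$meta$intensities$background))
})

test_that("biological phantom provides 20 boundary-crossing edge profiles", {
  ph <- make_biological_phantom(grid_shape = 96, seed = 1)
  prof <- ph$meta$edge_profiles
  expect_equal(nrow(prof), 20)
  ints <- ph$meta$intensities
  for (i in c(1, 7, 14, 20)) {
    p <- extract_line_profile(ph, c(prof$sx[i], prof$sy[i], prof$sz[i]),
                              c(prof$ex[i], prof$ey[i], prof$ez[i]), 49)
    # profile runs from liver out into body tissue
    expect_equal(p$value[1], ints$liver, tolerance = 0.1)
    expect_equal(tail(p$value, 1), ints$body, tolerance = 0.1)
  }
})

test_that("too-small grids for the biological phantom are refused", {
  expect_error(make_biological_phantom(grid_shape = 32), "too small")
})
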