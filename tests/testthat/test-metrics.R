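make_roi_volume <- function() {
  v <- srr_volume(array(50, c(30, 30, 30)), 1)
  set.seed(11)
  v$data[1:9, 1:9, 1:9] <- 100                      # signal: constant
  v$data[21:29, 21:29, 21:29] <- rnorm(729, 0, 10)  # noise: sd ~10
  v$data[1:9, 21:29, 1:9] <- 80 + rnorm(729, 0, 5)  # high
  v$data[21:29, 1:9, 1:9] <- 20 + rnorm(729, 0, 10) # low
  v
}

test_that("SNR matches its definition and is scale invariant", {
  v <- make_roi_volume()
  sig <- box_roi(c(1, 1, 1)); noi <- box_roi(c(21, 21, 21))
  expected <- 100 / sd(as.numeric(v$data[21:29, 21:29, 21:29]))
  expect_equal(compute_snr(v, sig, noi), expected, tolerance = 1e-12)
  v2 <- v; v2$data <- v$data * 3.7
  expect_equal(compute_snr(v2, sig, noi), expected, tolerance = 1e-12)
  # zero-mean signal on pure noise gives SNR near zero
  expect_lt(abs(compute_snr(v, noi, noi)), 0.2)
  flat <- srr_volume(array(1, c(12, 12, 12)), 1)
  expect_error(compute_snr(flat, box_roi(c(1, 1, 1)), box_roi(c(2, 2, 2))),
               "zero standard deviation")
})

test_that("CNR matches its definition and is symmetric", {
  v <- make_roi_volume()
  hi <- box_roi(c(1, 21, 1)); lo <- box_roi(c(21, 1, 1))
  vh <- as.numeric(v$data[1:9, 21:29, 1:9])
  vl <- as.numeric(v$data[21:29, 1:9, 1:9])
  expected <- abs(mean(vh) - mean(vl)) / max(sd(vh), sd(vl))
  expect_equal(compute_cnr(v, hi, lo), expected, tolerance = 1e-12)
  expect_equal(compute_cnr(v, lo, hi), expected, tolerance = 1e-12)
  expect_equal(compute_cnr(v, hi, hi), 0)
  expect_error(compute_cnr(srr_volume(array(1, c(12, 12, 12)), 1),
                           box_roi(c(1, 1, 1)), box_roi(c(2, 2, 2))),
               "zero standard deviation")
  # ROI guard
  expect_error(compute_cnr(v, box_roi(c(28, 1, 1)), lo), "outside")
})

test_that("line profiles interpolate exactly at voxel centers", {
  v <- srr_volume(array(7, c(8, 8, 8)), 1)
  p <- extract_line_profile(v, c(-2, 0, 0), c(2, 0, 0), 11)
  expect_true(all(p$value == 7))
  set.seed(3)
  v$data <- array(runif(512), c(8, 8, 8))
  # axis-aligned profile hitting voxel centers of row y=z=index 5
  start <- v$origin + c(0, 4, 4) * v$spacing
  end <- start + c(7, 0, 0) * v$spacing
  p <- extract_line_profile(v, start, end, 8)
  expect_equal(p$value, v$data[, 5, 5], tolerance = 1e-12)
  expect_equal(p$s_px, 0:7)
})

test_that("a profile across the phantom shows five minima at tube spacing", {
  ph <- make_resolution_phantom()
  pr <- ph$meta$tube_profile
  prof <- extract_line_profile(ph, pr$start, pr$end, 513)
  expect_gt(tube_modulation(prof, 5), 0.9)
  # adjacent tube troughs separated by the center-to-center distance
  low <- rle(prof$value < 50)
  ends <- cumsum(low$lengths)
  starts <- ends - low$lengths + 1
  troughs <- purrr::map_dbl(which(low$values),
                            function(i) mean(prof$s_px[starts[i]:ends[i]]))
  expect_length(troughs, 5)
  sep_px <- mean(diff(troughs))
  expect_equal(sep_px, ph$meta$center_spacing / ph$spacing[1],
               tolerance = 0.05)
})

test_that("noiseless sigmoid profiles are recovered to optimizer precision", {
  prof <- logistic_profile(a1 = 0, a2 = 1, a3 = 4.4, a4 = 10)
  fit <- fit_sigmoid_edge(prof)
  expect_true(fit$converged)
  expect_equal(fit$a3, 4.4, tolerance = 1e-6)
  expect_equal(fit$edge_width_pixels, 1, tolerance = 1e-6)
  # descending profiles are flipped so the slope stays positive
  desc <- prof; desc$value <- rev(prof$value)
  fit2 <- fit_sigmoid_edge(desc)
  expect_true(fit2$converged)
  expect_gt(fit2$a3, 0)
  expect_equal(fit2$a3, 4.4, tolerance = 1e-6)
})

test_that("sigmoid recovery under 2% noise has small median error", {
  errs <- vapply(1:50, function(s) {
    prof <- logistic_profile(a1 = 0, a2 = 1, a3 = 4.4, a4 = 10)
    prof$value <- prof$value + srrgeom:::with_local_seed(
      s, rnorm(nrow(prof), 0, 0.02))
    fit <- fit_sigmoid_edge(prof)
    if (fit$converged) abs(fit$a3 - 4.4) / 4.4 else NA_real_
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("an ideal step edge fits to a subvoxel-to-two-voxel width", {
  step <- c(rep(0, 12), rep(1, 12))
  fit <- fit_sigmoid_edge(step)
  expect_true(fit$converged)
  expect_lte(fit$edge_width_pixels, 2)
  expect_error(fit_sigmoid_edge(rep(1, 20)), "flat")
})

test_that("edge width is 4.4 over the slope and antitone in it", {
  f <- structure(list(a3 = 4.4), class = "sigmoid_fit")
  expect_equal(edge_width_pixels(f), 1)
  expect_equal(edge_width_pixels(2.2), 2)
  slopes <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(edge_width_pixels(slopes)) < 0))
  # the exact 10-90% rise of the logistic vs the rounded 4.4 constant
  ratio <- (2 * log(9)) / 4.4
  expect_gte(ratio, 0.998)
  expect_lte(ratio, 1.0)
})

test_that("mean edge width averages converged fits", {
  p1 <- logistic_profile(a3 = 4.4)
  p2 <- logistic_profile(a3 = 2.2)
  p3 <- logistic_profile(a3 = 4.4 / 3)
  res <- mean_edge_width(list(p1, p2, p3))
  expect_equal(res$mean_edge_width_pixels, 2, tolerance = 1e-4)
  expect_equal(res$n_converged, 3L)
  same <- mean_edge_width(rep(list(p2), 20))
  expect_equal(same$mean_edge_width_pixels, 2, tolerance = 1e-6)
  expect_equal(same$n_profiles, 20L)
})

test_that("stronger blur widens the measured boundary", {
  ph <- make_biological_phantom(grid_shape = 96, seed = 5)
  blur3 <- function(vol, fwhm_px) {
    k <- slice_profile_kernel(fwhm_px, 1)
    d <- vol$data
    for (ax in 1:3) {
      perm <- switch(ax, c(3, 2, 1), c(1, 3, 2), c(1, 2, 3))
      d <- aperm(array(srrgeom:::cpp_convolve_z(aperm(d, perm),
                                                dim(d)[perm], k),
                       dim(d)[perm]), order(perm))
    }
    out <- vol; out$data <- d; out
  }
  w2 <- mean_edge_width(blur3(ph, 2))$mean_edge_width_pixels
  w4 <- mean_edge_width(blur3(ph, 4))$mean_edge_width_pixels
  expect_gt(w4, w2)
})

test_that("tube modulation detects resolved, constant, and merged cases", {
  ph <- make_resolution_phantom()
  pr <- ph$meta$tube_profile
  prof <- extract_line_profile(ph, pr$start, pr$end, 513)
  expect_gt(tube_modulation(prof, 5), 0.9)
  expect_equal(tube_modulation(rep(3, 100), 5), 0)
  # smoothing until adjacent minima merge removes the modulation
  sep_samples <- ph$meta$center_spacing / ph$spacing[1] * 4  # 4 samples/px
  smoothed <- stats::filter(prof$value, rep(1, 3 * sep_samples) /
                              (3 * sep_samples), sides = 2)
  smoothed <- as.numeric(smoothed[!is.na(smoothed)])
  expect_equal(tube_modulation(smoothed, 5), 0)
})
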