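#' Box region of interest
#'
#' An axis-aligned box of voxels, given by the (1-based) index of its low
#' corner and its extent per axis. The conventional size for homogeneity
#' measurements is 9 x 9 x 9 voxels.
#'
#' @param corner Integer voxel index triple of the low corner.
#' @param size Integer extent triple (components >= 1).
#' @return A `box_roi` list.
#' @export
box_roi <- function(corner, size = c(9, 9, 9)) {
  corner <- as.integer(corner); size <- as.integer(size)
  if (length(corner) != 3L || length(size) != 3L || any(size < 1))
    stop("corner and size must be integer triples with size >= 1")
  structure(list(corner = corner, size = size), class = "box_roi")
}

roi_values <- function(volume, roi) {
  stopifnot(is_srr_volume(volume), inherits(roi, "box_roi"))
  hi <- roi$corner + roi$size - 1L
  if (any(roi$corner < 1L) || any(hi > dim(volume$data)))
    stop("ROI extends outside the volume")
  volume$data[roi$corner[1]:hi[1], roi$corner[2]:hi[2], roi$corner[3]:hi[3]]
}

#' Signal-to-noise ratio
#'
#' SNR = mean(signal ROI) / sd(noise ROI), with the noise standard
#' deviation taken from a background (signal-free) region. Invariant to
#' global intensity scaling. Note that for Rician (magnitude) noise the
#' background sd underestimates the true noise sigma by the Rayleigh
#' factor; with the package's default Gaussian noise model the estimate is
#' unbiased.
#'
#' @param volume An [srr_volume()].
#' @param signal_roi,noise_roi [box_roi()] regions inside the volume.
#' @return The ratio (unitless).
#' @export
compute_snr <- function(volume, signal_roi, noise_roi) {
  s <- mean(roi_values(volume, signal_roi))
  n <- sd(as.numeric(roi_values(volume, noise_roi)))
  if (n == 0)
    stop("noise ROI has zero standard deviation: SNR undefined")
  s / n
}

#' Contrast-to-noise ratio
#'
#' CNR = |mean(high) - mean(low)| / max(sd(high), sd(low)). Invariant to
#' global intensity scaling and shifting, and symmetric in the two ROIs.
#'
#' @param volume An [srr_volume()].
#' @param roi_high,roi_low [box_roi()] regions in high/low intensity
#'   tissue.
#' @return The ratio (unitless).
#' @export
compute_cnr <- function(volume, roi_high, roi_low) {
  vh <- as.numeric(roi_values(volume, roi_high))
  vl <- as.numeric(roi_values(volume, roi_low))
  denom <- max(sd(vh), sd(vl))
  if (denom == 0) stop("both ROIs have zero standard deviation: CNR undefined")
  abs(mean(vh) - mean(vl)) / denom
}

#' Sample an intensity profile along a line segment
#'
#' Trilinear interpolation of the volume at `n_samples` evenly spaced
#' points from `start_mm` to `end_mm` (physical coordinates). Sample
#' positions along the segment are reported in HR pixels (distance divided
#' by the first-axis voxel size), the unit in which edge widths are
#' quoted.
#'
#' @param volume An [srr_volume()].
#' @param start_mm,end_mm Physical endpoints, mm (length-3).
#' @param n_samples Number of samples (>= 2).
#' @return Tibble with `s_px` (position along the segment, HR pixels) and
#'   `value`.
#' @export
extract_line_profile <- function(volume, start_mm, end_mm, n_samples) {
  stopifnot(is_srr_volume(volume), n_samples >= 2)
  t <- seq(0, 1, length.out = n_samples)
  px <- start_mm[1] + t * (end_mm[1] - start_mm[1])
  py <- start_mm[2] + t * (end_mm[2] - start_mm[2])
  pz <- start_mm[3] + t * (end_mm[3] - start_mm[3])
  v <- interp_trilinear(volume, px, py, pz)
  len_mm <- sqrt(sum((end_mm - start_mm)^2))
  tibble::tibble(s_px = t * len_mm / volume$spacing[1], value = v)
}

# vectorized trilinear interpolation at physical points, clamped at edges
interp_trilinear <- function(volume, px, py, pz) {
  d <- dim(volume$data)
  ix <- (px - volume$origin[1]) / volume$spacing[1] + 1
  iy <- (py - volume$origin[2]) / volume$spacing[2] + 1
  iz <- (pz - volume$origin[3]) / volume$spacing[3] + 1
  ix <- pmin(pmax(ix, 1), d[1]); iy <- pmin(pmax(iy, 1), d[2])
  iz <- pmin(pmax(iz, 1), d[3])
  x0 <- pmin(floor(ix), d[1] - 1L); y0 <- pmin(floor(iy), d[2] - 1L)
  z0 <- pmin(floor(iz), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(ix))
  if (d[2] == 1L) y0 <- rep(1, length(iy))
  if (d[3] == 1L) z0 <- rep(1, length(iz))
  wx <- ix - x0; wy <- iy - y0; wz <- iz - z0
  g <- function(xi, yi, zi) volume$data[cbind(xi, yi, zi)]
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  (1 - wx) * (1 - wy) * (1 - wz) * g(x0, y0, z0) +
    wx * (1 - wy) * (1 - wz) * g(x1, y0, z0) +
    (1 - wx) * wy * (1 - wz) * g(x0, y1, z0) +
    wx * wy * (1 - wz) * g(x1, y1, z0) +
    (1 - wx) * (1 - wy) * wz * g(x0, y0, z1) +
    wx * (1 - wy) * wz * g(x1, y0, z1) +
    (1 - wx) * wy * wz * g(x0, y1, z1) +
    wx * wy * wz * g(x1, y1, z1)
}

#' Fit a sigmoid edge model to an intensity profile
#'
#' Nonlinear least-squares fit of the logistic edge model
#' `f(x) = a1 + a2 / (1 + exp(-a3 (x - a4)))`: `a1` baseline, `a2`
#' amplitude, `a3` slope (per HR pixel), `a4` edge location. Profiles that
#' descend are flipped in x before fitting so that `a3 > 0`. Starting
#' values come from the data: `a1` = minimum, `a2` = range, `a4` = the
#' half-range crossing, `a3` = 4.4 over the 10-90% crossing distance.
#' Levenberg-Marquardt fitting via [minpack.lm::nlsLM()]. A fit is flagged
#' non-converged (and excluded from downstream means) when the optimizer
#' fails, the fitted edge location leaves the profile, or the implied edge
#' width exceeds the profile length.
#'
#' The derived edge width is `4.4 / a3` HR pixels: the 10-90% rise length
#' of the logistic is `2 ln(9) / a3 = 4.394 / a3`, quoted with the
#' conventional two-significant-figure constant 4.4, so `a3 = 4.4`
#' corresponds to a rise length of one voxel.
#'
#' @param profile Tibble from [extract_line_profile()] (columns `s_px`,
#'   `value`) or a bare numeric vector (positions taken as 0, 1, 2, ...
#'   pixels).
#' @return A `sigmoid_fit` with fields `a1`-`a4`, `edge_width_pixels`,
#'   `residual_ss`, `converged`, `flipped`, `n`.
#' @export
fit_sigmoid_edge <- function(profile) {
  if (is.numeric(profile))
    profile <- tibble::tibble(s_px = seq_along(profile) - 1, value = profile)
  x <- profile$s_px
  y <- profile$value
  if (length(y) < 8) stop("profile needs >= 8 samples")
  rng <- diff(range(y))
  if (rng == 0) stop("flat profile: no edge to fit")

  # orient ascending so a3 > 0
  n <- length(y)
  q <- max(2L, floor(n / 4))
  flipped <- mean(head(y, q)) > mean(tail(y, q))
  if (flipped) x <- -rev(x) + max(x) else x <- x - min(x)
  if (flipped) y <- rev(y)

  yn <- (y - min(y)) / rng
  cross <- function(level) {
    idx <- which(yn >= level)[1]
    if (is.na(idx) || idx == 1) return(x[1])
    # linear interpolation between the bracketing samples
    x[idx - 1] + (level - yn[idx - 1]) / (yn[idx] - yn[idx - 1]) *
      (x[idx] - x[idx - 1])
  }
  x10 <- cross(0.1); x50 <- cross(0.5); x90 <- cross(0.9)
  rise0 <- max(x90 - x10, diff(range(x)) / (n - 1))
  start <- list(a1 = min(y), a2 = rng, a3 = 4.4 / rise0, a4 = x50)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      value ~ a1 + a2 / (1 + exp(-a3 * (s - a4))),
      data = data.frame(s = x, value = y),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )

  out <- list(a1 = NA_real_, a2 = NA_real_, a3 = NA_real_, a4 = NA_real_,
              edge_width_pixels = NA_real_, residual_ss = NA_real_,
              converged = FALSE, flipped = flipped, n = n,
              data = tibble::tibble(s_px = x, value = y))
  if (!is.null(fit)) {
    cf <- coef(fit)
    plausible <- is.finite(cf["a3"]) && cf["a3"] > 0 &&
      cf["a4"] >= min(x) && cf["a4"] <= max(x) &&
      4.4 / cf["a3"] <= diff(range(x))
    if (plausible) {
      out[c("a1", "a2", "a3", "a4")] <- as.list(unname(cf))
      out$edge_width_pixels <- 4.4 / cf[["a3"]]
      out$residual_ss <- sum(resid(fit)^2)
      out$converged <- TRUE
    }
  }
  structure(out, class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "<sigmoid_fit> a1=%.4g a2=%.4g a3=%.4g a4=%.4g; edge width %.3g px (n=%d)\n",
      x$a1, x$a2, x$a3, x$a4, x$edge_width_pixels, x$n))
  } else {
    cat("<sigmoid_fit> not converged\n")
  }
  invisible(x)
}

#' @rdname fit_sigmoid_edge
#' @param x A `sigmoid_fit`.
#' @param ... Unused.
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = c("a1", "a2", "a3", "a4"),
                 estimate = c(x$a1, x$a2, x$a3, x$a4))
}

#' @rdname fit_sigmoid_edge
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(edge_width_pixels = x$edge_width_pixels,
                 residual_ss = x$residual_ss, converged = x$converged,
                 flipped = x$flipped, n = x$n)
}

#' Edge width from a sigmoid fit
#'
#' `4.4 / a3` in HR pixels (the 10-90% rise length of the fitted logistic,
#' to two significant figures in the constant). Antitone in the slope
#' `a3`.
#'
#' @param fit A `sigmoid_fit`, or a bare numeric `a3` slope.
#' @return Width in HR pixels.
#' @export
edge_width_pixels <- function(fit) {
  if (inherits(fit, "sigmoid_fit")) return(4.4 / fit$a3)
  4.4 / fit
}

#' Mean edge width over a set of boundary profiles
#'
#' Extracts `n` line profiles across a boundary (supersampled at
#' `step_px` HR pixels to stabilize fits on sharp edges), fits the sigmoid
#' edge model to each, and averages the edge widths of the converged fits;
#' non-converged fits are dropped, not imputed, and the count is reported.
#'
#' @param volume An [srr_volume()], or a list of pre-extracted profiles
#'   (numeric vectors / profile tibbles), in which case `edge_profiles` is
#'   ignored.
#' @param edge_profiles Tibble of segments with columns `sx, sy, sz, ex,
#'   ey, ez` (mm), e.g. `meta$edge_profiles` of
#'   [make_biological_phantom()].
#' @param n Number of profiles to use (first `n` rows).
#' @param step_px Profile sampling step in HR pixels.
#' @return One-row tibble: `mean_edge_width_pixels`, `n_profiles`,
#'   `n_converged`.
#' @export
mean_edge_width <- function(volume, edge_profiles = NULL, n = 20,
                            step_px = 0.25) {
  if (is_srr_volume(volume)) {
    if (is.null(edge_profiles))
      edge_profiles <- volume$meta$edge_profiles
    if (is.null(edge_profiles))
      stop("no edge profiles supplied and none in the volume's meta")
    edge_profiles <- head(edge_profiles, n)
    profiles <- purrr::map(seq_len(nrow(edge_profiles)), function(i) {
      p <- edge_profiles[i, ]
      st <- c(p$sx, p$sy, p$sz); en <- c(p$ex, p$ey, p$ez)
      len_px <- sqrt(sum((en - st)^2)) / volume$spacing[1]
      extract_line_profile(volume, st, en,
                           n_samples = max(8, ceiling(len_px / step_px) + 1))
    })
  } else {
    profiles <- head(volume, n)
  }
  fits <- purrr::map(profiles, function(p) {
    tryCatch(fit_sigmoid_edge(p), error = function(e) NULL)
  })
  widths <- purrr::map_dbl(fits, function(f) {
    if (!is.null(f) && f$converged) f$edge_width_pixels else NA_real_
  })
  tibble::tibble(
    mean_edge_width_pixels = mean(widths, na.rm = TRUE),
    n_profiles = length(widths),
    n_converged = sum(!is.na(widths))
  )
}

#' Tube-resolvability score of a line profile
#'
#' Quantifies whether the dark tubes of the resolution phantom are
#' resolved along a profile crossing all tube centers. Local minima are
#' detected on the run-length-compressed profile; a minimum counts only if
#' its depth below the lower of its flanking local maxima is at least
#' `prominence_frac` of the profile's dynamic range (this keeps noise
#' wiggles from masquerading as tubes). If fewer than `n_tubes` qualifying
#' minima exist the tubes are unresolved and the score is 0; otherwise the
#' score is the mean depth of the `n_tubes` deepest minima divided by the
#' dynamic range, in [0, 1].
#'
#' @param profile Numeric vector or profile tibble (column `value`).
#' @param n_tubes Expected number of tubes.
#' @param prominence_frac Minimum prominence as a fraction of the dynamic
#'   range.
#' @return Modulation depth in [0, 1]; 0 means unresolved.
#' @export
tube_modulation <- function(profile, n_tubes, prominence_frac = 0.1) {
  v <- if (is.numeric(profile)) profile else profile$value
  rng <- diff(range(v))
  if (rng == 0 || n_tubes < 1) return(0)
  r <- rle(v)
  vals <- r$values
  m <- length(vals)
  if (m < 3) return(0)
  kind <- integer(m)  # -1 min, +1 max, 0 neither
  for (i in 2:(m - 1)) {
    if (vals[i] < vals[i - 1] && vals[i] < vals[i + 1]) kind[i] <- -1L
    if (vals[i] > vals[i - 1] && vals[i] > vals[i + 1]) kind[i] <- 1L
  }
  mins <- which(kind == -1L)
  if (length(mins) == 0) return(0)
  maxima <- which(kind == 1L)
  depth <- vapply(mins, function(i) {
    left <- maxima[maxima < i]
    right <- maxima[maxima > i]
    lv <- if (length(left)) vals[tail(left, 1)] else vals[1]
    rv <- if (length(right)) vals[right[1]] else vals[m]
    min(lv, rv) - vals[i]
  }, numeric(1))
  keep <- depth >= prominence_frac * rng
  if (sum(keep) < n_tubes) return(0)
  mean(sort(depth[keep], decreasing = TRUE)[seq_len(n_tubes)]) / rng
}
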