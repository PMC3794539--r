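#' Multislice acquisition model
#'
#' Parameters of the simulated 2D multislice acquisition. The through-plane
#' excitation profile is modelled as a 1D Gaussian whose FWHM equals the
#' slice thickness (a close match to the excitation profile of the gradient
#' echo sequences this emulates); in-plane resolution is left at the HR
#' grid resolution, since multislice small-animal protocols are 5-10x finer
#' in-plane than through-plane and only the slice axis is degraded.
#'
#' @param inplane_spacing In-plane voxel size, mm (= HR grid spacing).
#' @param slice_thickness Slice thickness, mm; must be >= inplane spacing.
#' @param blur_fwhm Slice-profile FWHM, mm. Default = slice thickness.
#' @param noise_sigma Additive noise sd, intensity units.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @return An `acquisition_model` list.
#' @export
acquisition_model <- function(inplane_spacing, slice_thickness,
                              blur_fwhm = slice_thickness,
                              noise_sigma = 0,
                              noise_model = c("gaussian", "rician")) {
  noise_model <- match.arg(noise_model)
  if (blur_fwhm <= 0) stop("blur_fwhm must be > 0")
  if (slice_thickness < inplane_spacing)
    stop("slice_thickness must be >= inplane_spacing (aspect ratio >= 1)")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(
    list(inplane_spacing = inplane_spacing,
         slice_thickness = slice_thickness,
         blur_fwhm = blur_fwhm,
         noise_sigma = noise_sigma,
         noise_model = noise_model),
    class = "acquisition_model"
  )
}

#' Discrete Gaussian slice-profile kernel
#'
#' Samples a Gaussian of the given FWHM (sigma = FWHM / (2 sqrt(2 ln 2)))
#' at `sample_spacing`, truncates at +/- 3 sigma (< 0.3% mass loss), and
#' renormalizes to unit sum so that convolution preserves constants.
#'
#' @param fwhm Full width at half maximum, mm.
#' @param sample_spacing Grid spacing at which the kernel is sampled, mm.
#' @return Odd-length numeric kernel summing to 1.
#' @export
slice_profile_kernel <- function(fwhm, sample_spacing) {
  if (fwhm <= 0 || sample_spacing <= 0)
    stop("fwhm and sample_spacing must be > 0")
  if (fwhm < sample_spacing / 2)
    warning("fwhm below half the sample spacing: kernel is essentially a delta")
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  hw <- ceiling(3 * sigma / sample_spacing - 1e-9)
  x <- (-hw:hw) * sample_spacing
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Simulate a low-resolution multislice stack from an HR volume
#'
#' The forward model of the reconstruction problem, in order: (1) map the
#' HR volume into the stack frame with [transform_volume()]; (2) convolve
#' along the slice-select (third) axis with the slice-profile kernel
#' sampled at the HR spacing; (3) point-sample the blurred volume at the
#' slice centers (decimation by the aspect ratio -- the blur carries all
#' partial-volume effect, so no slab averaging is applied on top); (4) add
#' noise. No in-plane blur or decimation is applied. Slice centers start at
#' half a slice thickness from the stack-frame volume edge, so the first
#' slice is centered in its slab, and are spaced by one slice thickness
#' (contiguous slices).
#'
#' @param hr An isotropic [srr_volume()] whose spacing equals
#'   `model$inplane_spacing`.
#' @param geometry One `srr_plan` row.
#' @param model An [acquisition_model()].
#' @param seed Optional seed for the noise realization.
#' @return An `lr_stack`: the slice data, its geometry and model, the
#'   slice-center positions (mm, stack frame), and the stack-frame HR grid
#'   it was sampled from (used as the upsampling target).
#' @export
simulate_lr_stack <- function(hr, geometry, model, seed = NULL) {
  stopifnot(is_srr_volume(hr), inherits(model, "acquisition_model"))
  stopifnot_isotropic(hr)
  s <- hr$spacing[1]
  if (abs(s - model$inplane_spacing) > 1e-8 * s)
    stop("HR spacing must equal the model's inplane_spacing")
  ar <- model$slice_thickness / model$inplane_spacing
  if (ar < 1 - 1e-9) stop("aspect ratio must be >= 1")
  if (is.data.frame(geometry)) geometry <- geometry_row(geometry, 1L)

  framed <- transform_volume(hr, geometry, "forward")
  kernel <- slice_profile_kernel(model$blur_fwhm, s)
  blurred <- if (length(kernel) > 1) {
    array(cpp_convolve_z(framed$data, dim(framed$data), kernel),
          dim = dim(framed$data))
  } else framed$data

  nz <- dim(blurred)[3]
  extent <- nz * s
  n_slices <- max(1L, floor(extent / model$slice_thickness + 1e-9))
  o3 <- framed$origin[3]
  # slice j centered in its slab: o3 - s/2 is the physical edge of the grid
  slice_pos <- o3 - s / 2 + (seq_len(n_slices) - 0.5) * model$slice_thickness
  zq <- (slice_pos - o3) / s + 1  # fractional voxel indices
  data <- sample_axis3(blurred, zq)

  if (model$noise_sigma > 0)
    data <- array(noisy_values(data, model$noise_sigma, model$noise_model,
                               seed), dim = dim(data))

  structure(
    list(data = data,
         geometry = geometry,
         model = model,
         slice_positions = slice_pos,
         frame_origin = framed$origin,
         frame_dim = dim(framed$data),
         frame_spacing = framed$spacing,
         background = hr$meta$background %||% 0),
    class = "lr_stack"
  )
}

#' @export
print.lr_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<lr_stack> %s (k=%d): %d x %d inplane @ %g mm, %d slices @ %g mm\n",
    x$geometry$kind, x$geometry$k, d[1], d[2], x$model$inplane_spacing,
    d[3], x$model$slice_thickness
  ))
  invisible(x)
}

# sample a 3D array along axis 3 at fractional voxel indices zq
# (linear between planes, clamped at the ends)
sample_axis3 <- function(arr, zq) {
  nz <- dim(arr)[3]
  zq <- pmin(pmax(zq, 1), nz)
  lo <- pmin(floor(zq), nz - 1L)
  if (nz == 1L) lo <- rep(1L, length(zq))
  w <- zq - lo
  out <- array(0, dim = c(dim(arr)[1:2], length(zq)))
  for (j in seq_along(zq)) {
    out[, , j] <- if (nz == 1L) arr[, , 1]
                  else arr[, , lo[j]] * (1 - w[j]) + arr[, , lo[j] + 1] * w[j]
  }
  out
}

#' Upsample an LR stack to an isotropic volume in its own frame
#'
#' Linear interpolation between slice centers along the slice-select axis
#' only; the in-plane grid is already at HR resolution and is preserved.
#' Samples beyond the first/last slice center are clamped to the nearest
#' slice rather than extrapolated, so no signal is fabricated outside the
#' acquired field of view. The target grid is the stack-frame HR grid the
#' stack was simulated from.
#'
#' @param stack An `lr_stack`.
#' @param target_spacing Isotropic target spacing, mm; must not exceed the
#'   slice thickness. Default: the stack's in-plane spacing.
#' @return An [srr_volume()] in the stack frame.
#' @export
upsample_stack <- function(stack, target_spacing = NULL) {
  stopifnot(inherits(stack, "lr_stack"))
  if (length(stack$slice_positions) == 0 || prod(dim(stack$data)) == 0)
    stop("empty stack")
  s <- stack$model$inplane_spacing
  if (is.null(target_spacing)) target_spacing <- s
  if (target_spacing > stack$model$slice_thickness + 1e-9)
    stop("target_spacing must be <= the slice thickness")
  if (abs(target_spacing - s) > 1e-8 * s)
    stop("target grid is the stack's inplane HR grid: target_spacing must equal the inplane spacing")

  nzt <- stack$frame_dim[3]
  zt <- stack$frame_origin[3] + (seq_len(nzt) - 1) * s
  pos <- stack$slice_positions
  # fractional index into the slice list, clamped (nearest-slice beyond ends)
  zq <- (zt - pos[1]) / stack$model$slice_thickness + 1
  data <- sample_axis3(stack$data, zq)
  srr_volume(data, spacing = rep(s, 3), origin = stack$frame_origin,
             meta = list(background = stack$background))
}
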