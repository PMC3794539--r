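#' Isotropic or anisotropic 3D image volume
#'
#' The basic container of the package: a 3D scalar intensity grid together
#' with its physical geometry. Axis order is (x, y, z); the array is stored
#' column-major so x varies fastest, matching NIfTI's on-disk order. Voxel
#' centers sit at `origin + (index - 1) * spacing` (1-based indices), and by
#' default the origin is chosen so the grid is centered on the physical
#' coordinate origin.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Per-axis voxel size in mm; scalar values are recycled.
#' @param origin Physical coordinate (mm) of the center of voxel `[1, 1, 1]`.
#'   Default centers the grid on (0, 0, 0).
#' @param meta Optional named list of generator metadata (region maps, ROI
#'   placements, suggested line profiles). Carried along, never interpreted
#'   by the container itself.
#'
#' @return An object of class `srr_volume`.
#' @export
srr_volume <- function(data, spacing, origin = NULL, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (!all(is.finite(data)))
    stop("all intensities must be finite")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes (mm)")
  d <- dim(data)
  if (any(d < 1L)) stop("each grid dimension must be >= 1")
  if (is.null(origin)) origin <- -(d - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("`origin` must have 3 components")
  structure(
    list(data = data, spacing = spacing, origin = origin, meta = meta),
    class = "srr_volume"
  )
}

#' @export
print.srr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<srr_volume> %d x %d x %d voxels, spacing %s mm\n",
    d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")
  ))
  cat(sprintf("  intensity range [%.4g, %.4g], origin (%s) mm\n",
              min(x$data), max(x$data),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

#' @export
as.array.srr_volume <- function(x, ...) x$data

#' @export
dim.srr_volume <- function(x) dim(x$data)

is_srr_volume <- function(x) inherits(x, "srr_volume")

# physical coordinates of voxel centers along one axis
axis_coords <- function(volume, axis) {
  n <- dim(volume$data)[axis]
  volume$origin[axis] + (seq_len(n) - 1) * volume$spacing[axis]
}

# physical coordinate of the grid's geometric center
volume_center <- function(volume) {
  volume$origin + (dim(volume$data) - 1) / 2 * volume$spacing
}

dynamic_range <- function(x) {
  if (is_srr_volume(x)) x <- x$data
  diff(range(x))
}

stopifnot_isotropic <- function(volume, tol = 1e-8) {
  s <- volume$spacing
  if (diff(range(s)) > tol * mean(s))
    stop("volume spacing must be isotropic for this operation")
  invisible(volume)
}

#' Write / read a volume as NIfTI-1
#'
#' Geometry round-trips through the NIfTI header: spacing in `pixdim`,
#' origin through the sform affine (diagonal, RAS-like, no rotation --
#' stack orientation is carried separately by the geometry objects).
#'
#' @param volume An [srr_volume()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` an
#'   [srr_volume()].
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_srr_volume(volume))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  affine <- diag(c(volume$spacing, 1))
  affine[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions: %s",
                 length(d), path))
  xf <- RNifti::xform(img)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- as.numeric(xf[1:3, 4])
  srr_volume(array(as.numeric(img), dim = d), spacing = spacing,
             origin = origin)
}

#' Add acquisition noise to a volume
#'
#' Gaussian noise adds a zero-mean perturbation of standard deviation
#' `sigma`. Rician noise returns the magnitude of the complex signal after
#' adding independent Gaussian noise of per-channel standard deviation
#' `sigma` to the real and imaginary parts -- the distribution of magnitude
#' MR images. In a zero-signal background the Rician model reduces to a
#' Rayleigh distribution with mean `sigma * sqrt(pi / 2)`.
#'
#' @param volume An [srr_volume()].
#' @param sigma Noise standard deviation, intensity units; must be >= 0.
#' @param model `"gaussian"` (default) or `"rician"`.
#' @param seed Optional integer seed; fixed seed gives a bit-reproducible
#'   realization without disturbing the caller's RNG stream.
#' @return A new [srr_volume()] with the same geometry.
#' @export
add_noise <- function(volume, sigma, model = c("gaussian", "rician"),
                      seed = NULL) {
  stopifnot(is_srr_volume(volume))
  model <- match.arg(model)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("`sigma` must be a single value >= 0")
  if (sigma == 0) return(volume)
  out <- volume
  out$data <- array(noisy_values(volume$data, sigma, model, seed),
                    dim = dim(volume$data))
  out
}

noisy_values <- function(x, sigma, model, seed = NULL) {
  if (sigma == 0) return(x)
  n <- length(x)
  with_local_seed(seed, {
    if (model == "gaussian") {
      x + rnorm(n, 0, sigma)
    } else {
      sqrt((x + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
    }
  })
}
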