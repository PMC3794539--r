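#' Acquisition plans for the three LR stack geometries
#'
#' An acquisition plan is a tibble with one row per low-resolution (LR)
#' stack geometry (columns `kind`, `k`, `shift_mm`, `rotation_deg`,
#' `plane`) plus plan-level attributes: `slice_thickness`, `inplane_spacing`
#' (mm), the voxel `aspect_ratio` = thickness / inplane spacing (the "N" of
#' a 1:1:N voxel), and `per_stack_minutes` for acquisition-time accounting.
#'
#' * `plan_shifted()` slides the same multislice stack along its
#'   slice-select axis in subvoxel steps: N = `round(thickness / inplane)`
#'   stacks, stack k shifted by `k * thickness / N` mm, so the N shifts
#'   tile one slice thickness exactly.
#' * `plan_rotational()` rotates the slice-select direction in equal
#'   angular increments about a fixed axis; a stack at theta and
#'   theta + 180 degrees samples identical planes, so the views must fit
#'   within a half rotation.
#' * `plan_orthogonal()` acquires three stacks with mutually orthogonal
#'   slice-select axes (axial, coronal, sagittal).
#'
#' @param slice_thickness LR slice thickness, mm.
#' @param inplane_spacing LR in-plane voxel size, mm (equals the target HR
#'   grid spacing).
#' @param per_stack_minutes Acquisition time of one LR stack, minutes.
#' @param n_views,increment_deg Number of rotational views and angular
#'   step in degrees; `n_views * increment_deg` must not exceed 180.
#' @return An `srr_plan` tibble.
#' @name acquisition_plans
NULL

new_plan <- function(geoms, slice_thickness, inplane_spacing,
                     per_stack_minutes) {
  if (slice_thickness < inplane_spacing || inplane_spacing <= 0)
    stop("need slice_thickness >= inplane_spacing > 0")
  if (nrow(geoms) == 0) stop("a plan needs at least one stack")
  structure(
    geoms,
    slice_thickness = slice_thickness,
    inplane_spacing = inplane_spacing,
    aspect_ratio = slice_thickness / inplane_spacing,
    per_stack_minutes = per_stack_minutes,
    class = c("srr_plan", class(tibble::tibble()))
  )
}

#' @rdname acquisition_plans
#' @export
plan_shifted <- function(slice_thickness, inplane_spacing,
                         per_stack_minutes = 3) {
  if (slice_thickness <= 0 || inplane_spacing <= 0)
    stop("slice_thickness and inplane_spacing must be > 0")
  n <- max(1L, as.integer(round(slice_thickness / inplane_spacing)))
  step <- slice_thickness / n
  geoms <- tibble::tibble(
    kind = "shifted",
    k = seq_len(n) - 1L,
    shift_mm = (seq_len(n) - 1L) * step,
    rotation_deg = NA_real_,
    plane = NA_character_
  )
  new_plan(geoms, slice_thickness, inplane_spacing, per_stack_minutes)
}

#' @rdname acquisition_plans
#' @export
plan_rotational <- function(slice_thickness, inplane_spacing,
                            n_views = 6, increment_deg = 30,
                            per_stack_minutes = 3) {
  if (n_views < 1) stop("n_views must be >= 1")
  if (n_views * increment_deg > 180)
    stop("n_views * increment_deg must be <= 180 degrees: views at theta and theta + 180 sample identical planes")
  geoms <- tibble::tibble(
    kind = "rotational",
    k = seq_len(n_views) - 1L,
    shift_mm = NA_real_,
    rotation_deg = (seq_len(n_views) - 1L) * increment_deg,
    plane = NA_character_
  )
  new_plan(geoms, slice_thickness, inplane_spacing, per_stack_minutes)
}

#' @rdname acquisition_plans
#' @export
plan_orthogonal <- function(slice_thickness, inplane_spacing,
                            per_stack_minutes = 3) {
  geoms <- tibble::tibble(
    kind = "orthogonal",
    k = 0:2,
    shift_mm = NA_real_,
    rotation_deg = NA_real_,
    plane = c("axial", "coronal", "sagittal")
  )
  new_plan(geoms, slice_thickness, inplane_spacing, per_stack_minutes)
}

#' @export
print.srr_plan <- function(x, ...) {
  cat(sprintf(
    "<srr_plan> %d %s stack(s), slice %g mm / inplane %g mm (AR 1:1:%g), %g min per stack\n",
    nrow(x), x$kind[1], attr(x, "slice_thickness"), attr(x, "inplane_spacing"),
    signif(attr(x, "aspect_ratio"), 4), attr(x, "per_stack_minutes")
  ))
  NextMethod()
}

#' Total acquisition time of a plan
#'
#' Number of stacks times the per-stack acquisition time.
#'
#' @param plan An `srr_plan`.
#' @return Minutes.
#' @export
estimate_acquisition_time <- function(plan) {
  nrow(plan) * attr(plan, "per_stack_minutes")
}

# one geometry row as a plain list
geometry_row <- function(plan, i) {
  g <- as.list(plan[i, , drop = FALSE])
  lapply(g, function(v) v[[1]])
}

# world-axis permutation for an orthogonal plane: stack frame = aperm(world,
# perm) so that the sliced world axis becomes stack axis 3
plane_permutation <- function(plane) {
  switch(plane,
    axial    = c(1L, 2L, 3L),  # slices along world z
    coronal  = c(1L, 3L, 2L),  # slices along world y
    sagittal = c(2L, 3L, 1L),  # slices along world x
    stop(sprintf("unknown orthogonal plane '%s'", plane))
  )
}

#' Apply or invert a stack geometry transform
#'
#' Maps a volume between the world frame and a stack's frame. In the stack
#' frame the slice-select direction is always the third array axis.
#' Orthogonal geometries are exact axis permutations (no interpolation);
#' shifted geometries resample along the slice axis; rotational geometries
#' resample in the x-z plane about the volume's geometric center (the
#' rotation axis is the volume's y axis, so the slice-select direction
#' sweeps the x-z plane). Samples falling outside the source grid take
#' `fill` (by default the phantom's declared background intensity when the
#' volume carries one, else 0 -- a zero fill would paint dark rinds into
#' background ROIs).
#'
#' @param volume An [srr_volume()]; spacing must be isotropic for
#'   rotational geometries.
#' @param geometry One row of an `srr_plan` (or an equivalent list with
#'   `kind` and its kind's fields).
#' @param direction `"forward"` (world to stack frame) or `"inverse"`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Out-of-support fill value.
#' @return An [srr_volume()] in the requested frame.
#' @export
transform_volume <- function(volume, geometry,
                             direction = c("forward", "inverse"),
                             interpolation = c("linear", "nearest"),
                             fill = NULL) {
  stopifnot(is_srr_volume(volume))
  direction <- match.arg(direction)
  interpolation <- match.arg(interpolation)
  if (is.data.frame(geometry)) geometry <- geometry_row(geometry, 1L)
  if (is.null(fill)) fill <- volume$meta$background %||% 0
  kind <- geometry$kind

  if (kind == "orthogonal") {
    perm <- plane_permutation(geometry$plane)
    if (direction == "inverse") perm <- order(perm)
    out <- volume
    out$data <- aperm(volume$data, perm)
    out$spacing <- volume$spacing[perm]
    out$origin <- volume$origin[perm]
    return(out)
  }

  if (kind == "shifted") {
    shift <- geometry$shift_mm
    if (direction == "inverse") shift <- -shift
    out <- volume
    out$data <- shift_axis3(volume$data, shift / volume$spacing[3], fill,
                            interpolation)
    return(out)
  }

  if (kind == "rotational") {
    stopifnot_isotropic(volume)
    theta <- geometry$rotation_deg * pi / 180
    if (direction == "inverse") theta <- -theta
    out <- volume
    out$data <- array(
      cpp_rotate_xz(volume$data, dim(volume$data), theta, fill,
                    interpolation == "nearest"),
      dim = dim(volume$data)
    )
    return(out)
  }

  stop(sprintf("unknown geometry kind '%s'", kind))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resample along axis 3 at fractional offset `shift_vox` (in voxels):
# out[, , k] = in at index k + shift_vox
shift_axis3 <- function(arr, shift_vox, fill, interpolation = "linear") {
  nz <- dim(arr)[3]
  if (interpolation == "nearest") shift_vox <- round(shift_vox)
  zq <- seq_len(nz) + shift_vox
  lo <- floor(zq)
  w <- zq - lo
  out <- array(fill, dim = dim(arr))
  for (k in seq_len(nz)) {
    l <- lo[k]
    if (l >= 1 && l <= nz) {
      sl <- arr[, , l] * (1 - w[k])
      if (w[k] > 0) {
        sl <- if (l + 1 <= nz) sl + arr[, , l + 1] * w[k]
              else sl + fill * w[k]
      }
      out[, , k] <- sl
    } else if (l == 0 && w[k] > 0) {
      out[, , k] <- fill * (1 - w[k]) + arr[, , 1] * w[k]
    }
  }
  out
}
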