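#' Configuration of the iterative back-projection loop
#'
#' The stopping rule halts when the residual e(i) -- the maximum over
#' stacks of a per-stack norm of (observed - simulated) -- falls below
#' `residual_threshold`, or after `max_iterations`. The default threshold,
#' chosen when `residual_threshold = NULL`, is 1e-3 times the dynamic range
#' of the observed stacks: tight enough that noiseless fixtures converge,
#' while noisy runs stop on the iteration cap (the noise floor keeps e(i)
#' above any tight threshold). `max_abs` is the default per-stack norm; it
#' pairs naturally with the outer maximum over stacks.
#'
#' @param max_iterations Iteration cap, >= 1.
#' @param residual_threshold Stopping threshold, intensity units (>= 0), or
#'   `NULL` for the dynamic-range default.
#' @param residual_norm `"max_abs"` or `"rms"` per-stack norm.
#' @param fill_value Intensity assigned to HR voxels outside every stack's
#'   support (rotational stacks do not cover the corners of the world
#'   grid). Use the scene's background intensity.
#' @return An `ibp_config` list.
#' @export
ibp_config <- function(max_iterations = 20, residual_threshold = NULL,
                       residual_norm = c("max_abs", "rms"),
                       fill_value = 0) {
  residual_norm <- match.arg(residual_norm)
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (!is.null(residual_threshold) && residual_threshold < 0)
    stop("residual_threshold must be >= 0")
  structure(
    list(max_iterations = as.integer(max_iterations),
         residual_threshold = residual_threshold,
         residual_norm = residual_norm,
         fill_value = fill_value),
    class = "ibp_config"
  )
}

# Binary support mask of a stack on the world grid: ones pushed through the
# forward transform and back, thresholded. Voxels whose round trip touches
# any out-of-support sample are excluded, which also trims the
# interpolation rind at rotated-volume borders.
stack_support <- function(stack) {
  ones <- srr_volume(array(1, dim = stack$frame_dim),
                     spacing = stack$frame_spacing)
  fwd <- transform_volume(ones, stack$geometry, "forward", fill = 0)
  back <- transform_volume(fwd, stack$geometry, "inverse", fill = 0)
  back$data > 1 - 1e-6
}

# Upsample a stack (or a difference stack) and return it on the world grid
# together with its support weight (cached on the stack when available).
backproject_stack <- function(stack) {
  up <- upsample_stack(stack)
  world <- transform_volume(up, stack$geometry, "inverse", fill = 0)
  list(data = world$data,
       weight = stack$support %||% stack_support(stack),
       spacing = world$spacing, origin = world$origin)
}

cache_supports <- function(stacks) {
  lapply(stacks, function(s) {
    if (is.null(s$support)) s$support <- stack_support(s)
    s
  })
}

#' Initial HR estimate from the LR stacks
#'
#' G(0) is the voxelwise mean over stacks of each stack upsampled to the
#' isotropic grid and inverse-transformed back to the world frame. Voxels
#' outside a stack's support are excluded from that voxel's mean (the
#' denominator adapts per voxel); voxels covered by no stack take
#' `config$fill_value`.
#'
#' @param stacks List of `lr_stack` objects sharing a world frame.
#' @param config An [ibp_config()].
#' @return An [srr_volume()] on the isotropic world grid.
#' @export
ibp_initialize <- function(stacks, config = ibp_config()) {
  if (length(stacks) == 0) stop("need at least one LR stack")
  stacks <- cache_supports(stacks)
  num <- NULL
  den <- NULL
  geomref <- NULL
  for (st in stacks) {
    bp <- backproject_stack(st)
    if (is.null(num)) {
      num <- bp$data * bp$weight
      den <- bp$weight + 0
      geomref <- bp
    } else {
      num <- num + bp$data * bp$weight
      den <- den + bp$weight
    }
  }
  out <- ifelse(den > 0, num / pmax(den, 1), config$fill_value)
  srr_volume(array(out, dim = dim(num)), spacing = geomref$spacing,
             origin = geomref$origin,
             meta = list(background = config$fill_value))
}

#' Simulate the LR acquisitions from an HR estimate
#'
#' Applies each stack's own geometry and acquisition model to the current
#' HR estimate through the noiseless forward model, yielding the simulated
#' stacks that the residual compares against the observations.
#'
#' @param hr_est Current HR estimate ([srr_volume()]).
#' @param stacks Observed `lr_stack` list (geometry/model templates).
#' @return List of simulated `lr_stack` objects.
#' @export
ibp_simulate <- function(hr_est, stacks) {
  lapply(stacks, function(st) {
    model <- st$model
    model$noise_sigma <- 0
    simulate_lr_stack(hr_est, st$geometry, model)
  })
}

#' Reconstruction residual e
#'
#' Per-stack norm (`max_abs` or `rms`) of observed minus simulated data,
#' maximized over stacks.
#'
#' @param observed,simulated Lists of `lr_stack` objects, same length and
#'   per-stack dimensions.
#' @param norm `"max_abs"` or `"rms"`.
#' @return Residual in intensity units.
#' @export
ibp_residual <- function(observed, simulated,
                         norm = c("max_abs", "rms")) {
  norm <- match.arg(norm)
  if (length(observed) != length(simulated))
    stop("observed and simulated stack lists differ in length")
  per_stack <- vapply(seq_along(observed), function(k) {
    d <- observed[[k]]$data - simulated[[k]]$data
    if (norm == "max_abs") max(abs(d)) else sqrt(mean(d^2))
  }, numeric(1))
  max(per_stack)
}

#' One back-projection update of the HR estimate
#'
#' Each difference stack (observed - simulated) is upsampled to the
#' isotropic grid with linear interpolation (the back-projection kernel
#' equals the upsampling interpolator; no separate filter), inverse
#' transformed to the world frame, averaged over stacks with a per-voxel
#' support-adapted 1/N, and added to the estimate with no damping (pure
#' Irani-Peleg averaging).
#'
#' @param hr_est Current HR estimate.
#' @param observed,simulated Lists of `lr_stack` objects.
#' @param config An [ibp_config()].
#' @return Updated [srr_volume()].
#' @export
ibp_update <- function(hr_est, observed, simulated, config = ibp_config()) {
  if (length(observed) != length(simulated))
    stop("observed and simulated stack lists differ in length")
  num <- 0
  den <- 0
  for (k in seq_along(observed)) {
    dstack <- observed[[k]]
    dstack$data <- observed[[k]]$data - simulated[[k]]$data
    dstack$background <- 0  # differences fall to zero outside support
    bp <- backproject_stack(dstack)
    num <- num + bp$data * bp$weight
    den <- den + bp$weight
  }
  delta <- ifelse(den > 0, num / pmax(den, 1), 0)
  out <- hr_est
  out$data <- hr_est$data + array(delta, dim = dim(hr_est$data))
  out
}

#' Irani-Peleg iterative back-projection reconstruction
#'
#' Alternates simulating the LR acquisitions from the current HR estimate,
#' measuring the residual e(i), and back-projecting the differences, until
#' e(i) drops below the threshold or the iteration cap is reached. The
#' loop is fully deterministic.
#'
#' @param stacks List of observed `lr_stack` objects.
#' @param config An [ibp_config()].
#' @return An `srr_fit`: `volume` (final estimate), `trace` (tibble with
#'   per-iteration `residual`, plus both `max_abs` and `rms` norms for
#'   audit), `converged`, `iterations_run`, and the resolved threshold.
#' @export
ibp_reconstruct <- function(stacks, config = ibp_config()) {
  if (length(stacks) == 0) stop("need at least one LR stack")
  stacks <- cache_supports(stacks)
  threshold <- config$residual_threshold
  if (is.null(threshold)) {
    dr <- diff(range(vapply(stacks, function(s) range(s$data),
                            numeric(2))))
    threshold <- 1e-3 * dr
  }

  est <- ibp_initialize(stacks, config)
  res_chosen <- res_max <- res_rms <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (i in seq_len(config$max_iterations)) {
    sim <- ibp_simulate(est, stacks)
    e_max <- ibp_residual(stacks, sim, "max_abs")
    e_rms <- ibp_residual(stacks, sim, "rms")
    e <- if (config$residual_norm == "max_abs") e_max else e_rms
    res_chosen <- c(res_chosen, e)
    res_max <- c(res_max, e_max)
    res_rms <- c(res_rms, e_rms)
    iters <- i
    if (e < threshold) {
      converged <- TRUE
      break
    }
    est <- ibp_update(est, stacks, sim, config)
    if (!all(is.finite(est$data)))
      stop(sprintf("non-finite values in the HR estimate at iteration %d", i))
  }

  structure(
    list(volume = est,
         trace = tibble::tibble(iteration = seq_len(iters),
                                residual = res_chosen,
                                residual_max_abs = res_max,
                                residual_rms = res_rms),
         converged = converged,
         iterations_run = iters,
         residual_threshold = threshold,
         config = config),
    class = "srr_fit"
  )
}

#' @export
print.srr_fit <- function(x, ...) {
  cat(sprintf(
    "<srr_fit> %d iteration(s), %s (final residual %.4g, threshold %.4g)\n",
    x$iterations_run,
    if (x$converged) "converged" else "stopped at iteration cap",
    tail(x$trace$residual, 1), x$residual_threshold
  ))
  invisible(x)
}

#' @rdname ibp_reconstruct
#' @param x An `srr_fit`.
#' @param ... Unused.
#' @export
tidy.srr_fit <- function(x, ...) x$trace

#' @rdname ibp_reconstruct
#' @export
glance.srr_fit <- function(x, ...) {
  tibble::tibble(
    iterations = x$iterations_run,
    converged = x$converged,
    final_residual = tail(x$trace$residual, 1),
    residual_threshold = x$residual_threshold,
    residual_norm = x$config$residual_norm
  )
}
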