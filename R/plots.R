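#' Plot a slice of a volume
#'
#' @param object An [srr_volume()].
#' @param axis Axis (1, 2, or 3) orthogonal to the displayed slice.
#' @param index Slice index; default the middle slice.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.srr_volume <- function(object, axis = 3, index = NULL, ...) {
  d <- dim(object$data)
  if (is.null(index)) index <- ceiling(d[axis] / 2)
  sl <- switch(axis,
               object$data[index, , ],
               object$data[, index, ],
               object$data[, , index])
  ax <- setdiff(1:3, axis)
  df <- tidyr::expand_grid(
    j = axis_coords(object, ax[2]),
    i = axis_coords(object, ax[1])
  )
  df$value <- as.vector(sl)
  lab <- c("x", "y", "z")
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0(lab[ax[1]], " (mm)"),
                  y = paste0(lab[ax[2]], " (mm)"), fill = "intensity")
}

#' Plot the convergence trace of an IBP reconstruction
#'
#' @param object An `srr_fit` from [ibp_reconstruct()].
#' @param ... Unused.
#' @return A ggplot of residual versus iteration (log scale).
#' @export
autoplot.srr_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$trace, c("residual_max_abs", "residual_rms"),
    names_to = "norm", names_prefix = "residual_", values_to = "residual"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$residual,
                                   colour = .data$norm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$residual_threshold,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "residual e(i)", colour = "norm")
}

#' Plot a sigmoid edge fit over its profile
#'
#' @param object A `sigmoid_fit` from [fit_sigmoid_edge()].
#' @param ... Unused.
#' @return A ggplot of the profile samples and, when the fit converged,
#'   the fitted logistic.
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data, ggplot2::aes(.data$s_px, .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "position (HR pixels)", y = "intensity")
  if (object$converged) {
    xs <- seq(min(object$data$s_px), max(object$data$s_px), length.out = 200)
    fitted <- object$a1 + object$a2 /
      (1 + exp(-object$a3 * (xs - object$a4)))
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(s_px = xs, value = fitted),
      colour = "red"
    )
  }
  p
}

#' Plot a comparison report
#'
#' Metric versus voxel aspect ratio, one panel per metric, colored by
#' acquisition geometry, averaged over replicates.
#'
#' @param object An `srr_report` from [run_comparison()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.srr_report <- function(object, ...) {
  df <- summarize_report(object) |>
    tidyr::pivot_longer(
      dplyr::any_of(c("snr", "cnr", "mean_edge_width_pixels",
                      "tube_modulation")),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(is.finite(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$aspect_ratio, .data$value,
                                   colour = .data$geometry)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "voxel aspect ratio (1:1:N)", y = NULL,
                  colour = "geometry")
}
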