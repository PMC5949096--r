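#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the residuals of an alignment solution
#'
#' One row per observed (marker, image) pair with measured, fitted and
#' residual coordinates in pixels.
#'
#' @param x a `tilt_alignment`.
#' @param ... unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.tilt_alignment <- function(x, ...) {
  stopifnot(!is.null(x$residuals))
  tibble::as_tibble(x$residuals)
}

#' One-row summary of an alignment solution
#'
#' @param x a `tilt_alignment`.
#' @param ... unused.
#' @return A tibble with `n_markers`, `n_images`, `n_obs`,
#'   `mean_residual`, `rms_residual`, `objective`, `motion_form`,
#'   `converged`.
#' @exportS3Method generics::glance
glance.tilt_alignment <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$markers),
    n_images = nrow(x$geometry),
    n_obs = if (is.null(x$residuals)) NA_integer_ else nrow(x$residuals),
    mean_residual = x$mean_residual,
    rms_residual = if (is.null(x$residuals)) NA_real_ else
      sqrt(mean(x$residuals$resid^2)),
    objective = x$objective,
    motion_form = if (is.null(x$motion)) "none" else x$motion$form,
    converged = x$fit$converged %||% NA
  )
}

#' Tidy a leave-one-out report
#'
#' @param x a `loo_report`.
#' @param ... unused.
#' @return The per-marker tibble.
#' @exportS3Method generics::tidy
tidy.loo_report <- function(x, ...) x$per_marker

#' One-row summary of a leave-one-out report
#'
#' @param x a `loo_report`.
#' @param ... unused.
#' @return A tibble with the LOO, standard and fitted residuals and the
#'   verdict.
#' @exportS3Method generics::glance
glance.loo_report <- function(x, ...) {
  tibble::tibble(loo_residual = x$loo_residual,
                 reference_standard_residual =
                   x$reference_standard_residual,
                 fitted_residual = x$fitted_residual,
                 verdict = x$verdict)
}

#' Residual-versus-acquisition diagnostic plot
#'
#' The averaged residual per acquired image (the motion fingerprint of a
#' tilt-series): highest at the start of each branch under beam-induced
#' doming, flattened by a motion-aware fit.
#'
#' @param object a `tilt_alignment`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tilt_alignment <- function(object, ...) {
  tab <- residual_vs_acquisition(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$acq_index,
                                    y = .data$mean_residual,
                                    colour = factor(.data$branch))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "acquired image", y = "mean residual (px)",
                  colour = "branch") +
    ggplot2::theme_minimal()
}

#' Per-marker leave-one-out residual plot
#'
#' @param object a `loo_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.loo_report <- function(object, ...) {
  ggplot2::ggplot(object$per_marker,
                  ggplot2::aes(x = stats::reorder(.data$marker,
                                                  .data$loo_residual),
                               y = .data$loo_residual)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$reference_standard_residual,
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "LOO residual (px)",
                  caption = "dashed: standard-alignment mean residual") +
    ggplot2::theme_minimal()
}

#' Compare residual-versus-acquisition curves of several fits
#'
#' @param ... named `tilt_alignment` objects (names label the curves).
#' @return A ggplot object.
#' @export
plot_residual_curves <- function(...) {
  sols <- list(...)
  stopifnot(length(sols) >= 1, !is.null(names(sols)))
  tabs <- dplyr::bind_rows(lapply(sols, residual_vs_acquisition),
                           .id = "fit")
  ggplot2::ggplot(tabs, ggplot2::aes(x = .data$acq_index,
                                     y = .data$mean_residual,
                                     colour = .data$fit)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "acquired image", y = "mean residual (px)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
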