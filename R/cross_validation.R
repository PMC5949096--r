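#' Leave-one-out cross-validation of the motion model
#'
#' Assesses whether the fitted deformation surfaces generalise beyond the
#' fiducials used to fit them. Each marker in turn is left out of the
#' motion fit; its positions through the tilt-series are then predicted
#' from the model fitted to the remaining markers, and the mean distance to
#' its measured positions is recorded. The LOO residual is the average of
#' these per-marker prediction errors. A LOO residual below the standard
#' (motion-free) mean residual validates the model over the area covered by
#' the fiducials; a larger one flags over-fitting (scarce or poorly
#' distributed markers).
#'
#' By default only the per-image motion fit (step 2) is redone per fold,
#' keeping the step-1 marker coordinates and image parameters from the full
#' fit; `refit_step1 = TRUE` redoes the standard alignment per fold as
#' well (predictions are still evaluated at the full-fit marker
#' coordinates).
#'
#' @inheritParams fit_motion
#' @param refit_step1 redo the standard alignment within each fold.
#' @param pooling `"marker"` (mean per held-out marker, then mean over
#'   markers) or `"pooled"` (mean over all held-out observations).
#' @return An object of class `loo_report`: list with `per_marker` (tibble
#'   `marker`, `n_obs`, `loo_residual`), `loo_residual`,
#'   `reference_standard_residual`, `fitted_residual` and `verdict`
#'   (`TRUE` when `loo_residual < reference_standard_residual`).
#' @export
loo_residual <- function(sol1, tracks, degree = 2, z_degree = 0,
                         mask_kind = "full", gauge_constant = TRUE,
                         refit_step1 = FALSE,
                         pooling = c("marker", "pooled")) {
  stopifnot(inherits(sol1, "tilt_alignment"))
  pooling <- match.arg(pooling)
  ids <- sort(unique(tracks$marker))
  if (length(ids) < 2)
    stop("leave-one-out needs at least two markers", call. = FALSE)
  # reference: motion-free residual at the step-1 solution
  base <- residual_table(sol1$markers, sol1$geometry, NULL, tracks)
  full_fit <- suppressMessages(
    fit_motion(sol1, tracks, degree, z_degree, mask_kind, gauge_constant))
  per <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    j <- ids[k]
    held <- tracks[tracks$marker == j, ]
    rest <- tracks[tracks$marker != j, ]
    rest <- marker_tracks(tibble::as_tibble(rest))
    sol_ref <- if (refit_step1) {
      standard_align(rest, sol1$geometry, refine = sol1$fit$refine %||%
                       character(0))
    } else sol1
    fold <- suppressMessages(
      fit_motion(sol_ref, rest, degree, z_degree, mask_kind, gauge_constant))
    # predict the held-out marker at its full-fit 3D coordinates
    mk <- sol1$markers[sol1$markers$marker == j, ]
    pred <- predict_pairs(mk, fold$geometry, fold$motion,
                          held[c("marker", "image")])
    d <- sqrt((held$u - pred$u)^2 + (held$v - pred$v)^2)
    per[[k]] <- tibble::tibble(marker = j, n_obs = nrow(held),
                               loo_residual = mean(d), sum_d = sum(d))
  }
  per <- dplyr::bind_rows(per)
  loo <- if (pooling == "marker") mean(per$loo_residual)
         else sum(per$sum_d) / sum(per$n_obs)
  per$sum_d <- NULL
  structure(list(per_marker = per,
                 loo_residual = loo,
                 reference_standard_residual = mean(base$resid),
                 fitted_residual = full_fit$mean_residual,
                 verdict = loo < mean(base$resid),
                 pooling = pooling),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf(
    "<loo_report> LOO residual %.4f px (standard %.4f, fitted %.4f): %s\n",
    x$loo_residual, x$reference_standard_residual, x$fitted_residual,
    if (x$verdict) "model validated" else "possible over-fit"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
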