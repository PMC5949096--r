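# Core least-squares machinery shared by the alignment steps.

# minimum-norm least-squares solve; rank decided by a relative singular
# value threshold so exactly-degenerate directions (gauge, beam-parallel
# motion) get the zero component.
solve_minnorm <- function(a, b, tol = 1e-10) {
  if (ncol(a) == 0) return(numeric(0))
  sv <- svd(a)
  keep <- sv$d > tol * max(sv$d, 0)
  if (!any(keep)) return(numeric(ncol(a)))
  drop(sv$v[, keep, drop = FALSE] %*%
         ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

# predicted (u, v) for a set of (marker, image) pairs given markers
# (tibble marker,x,y,z), geometry and an optional motion model
predict_pairs <- function(markers, geometry, motion, pairs) {
  rmat <- as.matrix(markers[c("x", "y", "z")])
  rownames(rmat) <- as.character(markers$marker)
  out_u <- numeric(nrow(pairs)); out_v <- numeric(nrow(pairs))
  for (i in unique(pairs$image)) {
    sel <- pairs$image == i
    g <- geometry[i, ]
    m <- projection_matrix(g)
    r <- rmat[as.character(pairs$marker[sel]), , drop = FALSE]
    if (!is.null(motion) && motion$form == "3d") {
      r <- r + eval_motion(motion, i, r)
    }
    p <- r %*% t(m)
    if (!is.null(motion) && motion$form == "2d") {
      p <- p + eval_motion(motion, i, rmat[as.character(pairs$marker[sel]), ,
                                           drop = FALSE])
    }
    out_u[sel] <- p[, 1] + g$du
    out_v[sel] <- p[, 2] + g$dv
  }
  tibble::tibble(marker = pairs$marker, image = pairs$image,
                 u = out_u, v = out_v)
}

residual_table <- function(markers, geometry, motion, tracks) {
  pred <- predict_pairs(markers, geometry, motion,
                        tracks[c("marker", "image")])
  tibble::tibble(
    marker = tracks$marker, image = tracks$image,
    u_obs = tracks$u, v_obs = tracks$v,
    u_fit = pred$u, v_fit = pred$v,
    ru = tracks$u - pred$u, rv = tracks$v - pred$v,
    resid = sqrt((tracks$u - pred$u)^2 + (tracks$v - pred$v)^2)
  )
}

#' Assemble an alignment solution from known parameters
#'
#' Builds a `tilt_alignment` object from explicit marker coordinates, image
#' geometry and (optionally) a motion model, recomputing residuals against
#' a track table if one is given. This is the entry point for adopting
#' parameters from an external alignment or from a simulation truth bundle.
#'
#' @param markers tibble with columns `marker`, `x`, `y`, `z` (pixels,
#'   sample frame).
#' @param geometry a [tilt_geometry()].
#' @param motion a [motion_model()] or `NULL`.
#' @param tracks a [marker_tracks()] table, or `NULL`.
#' @param fit optional list of fit metadata.
#' @return An object of class `tilt_alignment`.
#' @export
alignment_solution <- function(markers, geometry, motion = NULL,
                               tracks = NULL, fit = list()) {
  markers <- tibble::as_tibble(markers)
  stopifnot(all(c("marker", "x", "y", "z") %in% names(markers)))
  sol <- structure(list(markers = markers, geometry = geometry,
                        motion = motion, residuals = NULL,
                        mean_residual = NA_real_, objective = NA_real_,
                        fit = fit),
                   class = "tilt_alignment")
  if (!is.null(tracks)) sol <- refresh_residuals(sol, tracks)
  sol
}

refresh_residuals <- function(sol, tracks) {
  res <- residual_table(sol$markers, sol$geometry, sol$motion, tracks)
  sol$residuals <- res
  sol$mean_residual <- mean(res$resid)
  sol$objective <- sum(res$ru^2 + res$rv^2)
  sol
}

#' @export
print.tilt_alignment <- function(x, ...) {
  cat(sprintf(
    "<tilt_alignment> %d markers, %d images, motion: %s\n",
    nrow(x$markers), nrow(x$geometry),
    if (is.null(x$motion)) "none"
    else sprintf("%s D=%d Dz=%d", x$motion$form, x$motion$degree,
                 x$motion$z_degree)))
  if (!is.null(x$residuals))
    cat(sprintf("  mean residual %.4f px over %d observations\n",
                x$mean_residual, nrow(x$residuals)))
  invisible(x)
}

#' Predicted fiducial positions of an alignment solution
#'
#' Evaluates the fitted projection model `p = M r + S(r) + d` (motion absent
#' reduces to the standard model `p = M r + d`) at every observed
#' (marker, image) pair of the solution.
#'
#' @param sol a `tilt_alignment`.
#' @return A tibble with columns `marker`, `image`, `u`, `v` (pixels).
#' @export
predict_positions <- function(sol) {
  stopifnot(inherits(sol, "tilt_alignment"), !is.null(sol$residuals))
  predict_pairs(sol$markers, sol$geometry, sol$motion,
                sol$residuals[c("marker", "image")])
}

#' Sum-of-squares alignment objective
#'
#' The scalar minimised by the alignment: the sum over observed
#' (marker, image) pairs of the squared distance between measured and
#' predicted positions, in pixels squared.
#'
#' @param sol a `tilt_alignment`.
#' @param tracks a [marker_tracks()] table.
#' @return Non-negative scalar (pixels^2); zero iff the fit is exact.
#' @export
objective <- function(sol, tracks) {
  stopifnot(inherits(sol, "tilt_alignment"))
  if (!all(tracks$marker %in% sol$markers$marker))
    stop("tracks contain markers absent from the solution", call. = FALSE)
  if (any(tracks$image > nrow(sol$geometry)))
    stop("tracks reference images beyond the tilt-series", call. = FALSE)
  pred <- predict_pairs(sol$markers, sol$geometry, sol$motion,
                        tracks[c("marker", "image")])
  sum((tracks$u - pred$u)^2 + (tracks$v - pred$v)^2)
}

#' Standard fiducial tilt-series alignment (step 1)
#'
#' Solves the classical fiducial-based alignment: finds 3D marker
#' coordinates `r_j` and per-image shifts `d_i` (optionally refining
#' in-plane rotation, tilt angle and magnification) minimising the sum of
#' squared distances between measured and projected marker positions. With
#' no per-image parameter refinement the problem is linear in `(r_j, d_i)`
#' and is solved directly by minimum-norm least squares; with refinement a
#' Levenberg-Marquardt iteration with analytic Jacobian is used, started
#' from the linear solution.
#'
#' The translational gauge freedom (moving all markers by a constant while
#' compensating with the shifts) is fixed by pinning the marker centroid to
#' the origin. When rotation, tilt or magnification are refined the image
#' nearest 0 deg keeps its input value, removing the corresponding global
#' degeneracies.
#'
#' @param tracks a [marker_tracks()] table.
#' @param geometry initial [tilt_geometry()] (tilt angles, in-plane
#'   rotations; shifts are re-estimated).
#' @param refine character subset of
#'   `c("rotation", "tilt", "magnification")`.
#' @param max_iter,ftol Levenberg-Marquardt controls (refinement path only).
#' @return A `tilt_alignment` with fitted markers, shifts, residuals and a
#'   `fit` report (convergence, iterations, measurement/unknown counts).
#' @export
standard_align <- function(tracks, geometry, refine = character(0),
                           max_iter = 200, ftol = 1e-10) {
  stopifnot(inherits(tracks, "marker_tracks"))
  if (length(refine))
    refine <- match.arg(refine, c("rotation", "tilt", "magnification"),
                        several.ok = TRUE)
  if (any(tracks$image < 1 | tracks$image > nrow(geometry)))
    stop("tracks reference images outside the geometry", call. = FALSE)
  ids <- sort(unique(tracks$marker))
  nm <- length(ids)
  images_used <- sort(unique(tracks$image))
  nobs <- nrow(tracks)
  n_unknown <- 3L * nm + 2L * length(images_used) +
    length(refine) * (length(images_used) - 1L)
  n_gauge <- 3L
  if (2L * nobs <= n_unknown - n_gauge)
    stop(sprintf(paste0("under-determined alignment: %d measurements for %d",
                        " unknowns (deficit %d)"),
                 2L * nobs, n_unknown - n_gauge,
                 n_unknown - n_gauge - 2L * nobs + 1L), call. = FALSE)

  ji <- match(tracks$marker, ids)
  ii <- match(tracks$image, images_used)

  # --- linear solve for r, d with geometry angles fixed -------------------
  pm <- projection_matrices(geometry)
  p <- 3L * nm + 2L * length(images_used)
  a <- matrix(0, 2L * nobs, p)
  b <- numeric(2L * nobs)
  for (k in seq_len(nobs)) {
    m <- pm[[tracks$image[k]]]
    ru <- 2L * k - 1L; rv <- 2L * k
    cols <- 3L * (ji[k] - 1L) + 1:3
    a[ru, cols] <- m[1, ]; a[rv, cols] <- m[2, ]
    a[ru, 3L * nm + 2L * (ii[k] - 1L) + 1L] <- 1
    a[rv, 3L * nm + 2L * (ii[k] - 1L) + 2L] <- 1
    b[ru] <- tracks$u[k]; b[rv] <- tracks$v[k]
  }
  x0 <- solve_minnorm(a, b)
  rmat <- matrix(x0[seq_len(3L * nm)], nm, 3, byrow = TRUE)
  dmat <- matrix(x0[3L * nm + seq_len(2L * length(images_used))],
                 length(images_used), 2, byrow = TRUE)
  converged <- TRUE; niter <- 0L

  geom <- geometry
  if (length(refine)) {
    ref_img <- images_used[which.min(abs(geometry$tilt_deg[images_used]))]
    par0 <- c(t(rmat))
    par0 <- c(par0, c(t(dmat)))
    free <- list()
    for (what in refine) {
      v0 <- switch(what, rotation = geometry$psi_deg,
                   tilt = geometry$tilt_deg, magnification = geometry$mag)
      free[[what]] <- images_used[images_used != ref_img]
      par0 <- c(par0, v0[free[[what]]])
    }
    unpack <- function(par) {
      r <- matrix(par[seq_len(3L * nm)], nm, 3, byrow = TRUE)
      d <- matrix(par[3L * nm + seq_len(2L * length(images_used))],
                  length(images_used), 2, byrow = TRUE)
      g <- geometry
      off <- 3L * nm + 2L * length(images_used)
      for (what in refine) {
        idx <- free[[what]]
        vals <- par[off + seq_along(idx)]; off <- off + length(idx)
        if (what == "rotation") g$psi_deg[idx] <- vals
        if (what == "tilt") g$tilt_deg[idx] <- vals
        if (what == "magnification") g$mag[idx] <- vals
      }
      g$du[images_used] <- d[, 1]; g$dv[images_used] <- d[, 2]
      list(r = r, d = d, g = g)
    }
    resid_fn <- function(par) {
      st <- unpack(par)
      pmx <- projection_matrices(st$g)
      e <- numeric(2L * nobs)
      for (k in seq_len(nobs)) {
        m <- pmx[[tracks$image[k]]]
        pr <- m %*% st$r[ji[k], ] + st$d[ii[k], ]
        e[2L * k - 1L] <- tracks$u[k] - pr[1]
        e[2L * k] <- tracks$v[k] - pr[2]
      }
      e
    }
    jac_fn <- function(par) {
      st <- unpack(par)
      g <- st$g
      np <- length(par)
      jcb <- matrix(0, 2L * nobs, np)
      pr2 <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)  # P
      for (i in images_used) {
        th <- deg2rad(g$tilt_deg[i]); ps <- deg2rad(g$psi_deg[i])
        al <- deg2rad(g$alpha_deg[i]); mg <- g$mag[i]
        ry <- rotation_matrix(g$tilt_deg[i], 0, 0)
        rz <- rotation_matrix(0, g$psi_deg[i], 0)
        rx <- rotation_matrix(0, 0, g$alpha_deg[i])
        drz <- matrix(c(-sin(ps), -cos(ps), 0, cos(ps), -sin(ps), 0,
                        0, 0, 0), 3, 3, byrow = TRUE) * pi / 180
        dry <- matrix(c(-sin(th), 0, cos(th), 0, 0, 0,
                        -cos(th), 0, -sin(th)), 3, 3, byrow = TRUE) * pi / 180
        m <- mg * pr2 %*% rz %*% ry %*% rx
        dpsi <- mg * pr2 %*% drz %*% ry %*% rx
        dth <- mg * pr2 %*% rz %*% dry %*% rx
        dmag <- pr2 %*% rz %*% ry %*% rx
        sel <- which(tracks$image == i)
        iu <- ii[sel[1]]
        for (k in sel) {
          rj <- st$r[ji[k], ]
          rows <- c(2L * k - 1L, 2L * k)
          jcb[rows, 3L * (ji[k] - 1L) + 1:3] <- -m
          jcb[rows, 3L * nm + 2L * (iu - 1L) + 1:2] <- -diag(2)
          off <- 3L * nm + 2L * length(images_used)
          for (what in refine) {
            idx <- free[[what]]
            pos <- match(i, idx)
            if (!is.na(pos)) {
              dd <- switch(what, rotation = dpsi, tilt = dth,
                           magnification = dmag)
              jcb[rows, off + pos] <- -drop(dd %*% rj)
            }
            off <- off + length(idx)
          }
        }
      }
      jcb
    }
    fit <- minpack.lm::nls.lm(par0, fn = resid_fn, jac = jac_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = max_iter, ftol = ftol,
                                ptol = 1e-12))
    st <- unpack(fit$par)
    rmat <- st$r; dmat <- st$d; geom <- st$g
    converged <- fit$info %in% 1:4
    niter <- fit$niter
  }

  # translational gauge: marker centroid at the origin
  ctr <- colMeans(rmat)
  rmat <- sweep(rmat, 2, ctr)
  pm <- projection_matrices(geom)
  for (w in seq_along(images_used)) {
    dmat[w, ] <- dmat[w, ] + drop(pm[[images_used[w]]] %*% ctr)
  }
  geom$du[images_used] <- dmat[, 1]
  geom$dv[images_used] <- dmat[, 2]

  markers <- tibble::tibble(marker = ids, x = rmat[, 1], y = rmat[, 2],
                            z = rmat[, 3])
  sol <- alignment_solution(markers, geom, motion = NULL, tracks = tracks,
                            fit = list(method = if (length(refine))
                                         "levenberg-marquardt" else "linear",
                                       refine = refine,
                                       converged = converged,
                                       iterations = niter,
                                       n_obs = nobs,
                                       n_unknowns = n_unknown - n_gauge))
  sol$fit$ratio_obs_unknowns <- 2 * nobs / (n_unknown - n_gauge)
  sol
}

# fallback ladder of per-image term masks: each entry is a logical mask over
# the requested term table, monotonically shrinking
fallback_masks <- function(degree, z_degree, mask_kind, gauge_constant) {
  tt <- poly_terms(degree, z_degree)
  base <- term_mask(mask_kind, degree, z_degree)
  if (gauge_constant) base <- base & !(tt$m == 0 & tt$n == 0 & tt$l == 0)
  steps <- list(requested = base)
  for (kind in c("pure_z_only", "pure_terms")) {
    mk <- term_mask(kind, degree, z_degree) & base
    if (sum(mk) < sum(steps[[length(steps)]])) steps[[kind]] <- mk
  }
  lin <- base & (tt$m + tt$n + tt$l <= 1)
  if (sum(lin) < sum(steps[[length(steps)]])) steps[["linear"]] <- lin
  steps[["none"]] <- rep(FALSE, nrow(tt))
  steps
}

#' Fit the per-image motion polynomials (step 2)
#'
#' Holding the step-1 solution (marker coordinates, projection matrices and
#' shifts) fixed, fits per tilt image the pair of image-plane polynomial
#' surfaces `(Su_i, Sv_i)` to the step-1 residuals by exact linear least
#' squares on the monomial design matrix evaluated at the fitted marker
#' positions. Because the zero polynomial is always feasible, the
#' motion-aware mean residual never exceeds the step-1 one.
#'
#' The constant terms of `Su`/`Sv` are degenerate with the per-image shift
#' `d_i`; by default they are gauge-masked to zero (`gauge_constant = TRUE`)
#' and `d_i` keeps the global shift. Marker coordinates are normalised by
#' their maximum absolute value inside the solver and coefficients rescaled
#' back to pixel units. Images with too few observations for the requested
#' family fall back automatically through smoother families
#' (pure-z-terms, pure terms, linear, none); fallbacks are recorded in
#' `fit$fallback`.
#'
#' @param sol1 a `tilt_alignment` from [standard_align()] (or adopted via
#'   [alignment_solution()] / [import_external_alignment()]).
#' @param tracks the [marker_tracks()] table.
#' @param degree,z_degree polynomial degree `D` and z-degree `Dz`
#'   (`z_degree = 0` bivariate, `z_degree = degree` trivariate).
#' @param mask_kind `"full"`, `"pure_terms"` or `"pure_z_only"`.
#' @param gauge_constant mask the constant terms (recommended).
#' @param refit_shifts also refit `d_i` jointly with the coefficients
#'   (experimental; off by default).
#' @return A `tilt_alignment` with `motion` set (2D form) and residuals
#'   recomputed.
#' @export
fit_motion <- function(sol1, tracks, degree = 2, z_degree = 0,
                       mask_kind = "full", gauge_constant = TRUE,
                       refit_shifts = FALSE) {
  fit_motion_impl(sol1, tracks, degree, z_degree, mask_kind, gauge_constant,
                  refit_shifts, form = "2d")
}

#' Fit the motion in the 3D sample-frame form
#'
#' Same step-2 fit as [fit_motion()], but parameterised by the triad
#' `(dx_i, dy_i, dz_i)` of sample-frame surfaces, solved per image by
#' minimum-norm linear least squares. The projection makes the beam-parallel
#' combination of the triad unobservable (it lies in the null space of the
#' design), so the minimum-norm solution yields per-point 3D shift vectors
#' that are exactly perpendicular to the beam; predicted positions and
#' residuals are identical to the 2D form.
#'
#' @inheritParams fit_motion
#' @return A `tilt_alignment` with `motion` set (3D form).
#' @export
fit_motion_3d <- function(sol1, tracks, degree = 2, z_degree = 0,
                          mask_kind = "full", gauge_constant = TRUE,
                          refit_shifts = FALSE) {
  fit_motion_impl(sol1, tracks, degree, z_degree, mask_kind, gauge_constant,
                  refit_shifts, form = "3d")
}

fit_motion_impl <- function(sol1, tracks, degree, z_degree, mask_kind,
                            gauge_constant, refit_shifts, form) {
  stopifnot(inherits(sol1, "tilt_alignment"))
  tt <- poly_terms(degree, z_degree)
  nc <- nrow(tt)
  steps <- fallback_masks(degree, z_degree, mask_kind, gauge_constant)
  rmat <- as.matrix(sol1$markers[c("x", "y", "z")])
  rownames(rmat) <- as.character(sol1$markers$marker)
  scale <- max(abs(rmat), 1)
  rnorm_ <- rmat / scale
  # step-1 (motion-free) residuals at the frozen solution
  base <- residual_table(sol1$markers, sol1$geometry, NULL, tracks)
  n_img <- nrow(sol1$geometry)
  ncomp <- if (form == "3d") 3L else 2L
  coefs <- replicate(n_img, matrix(0, nc, ncomp), simplify = FALSE)
  dshift <- matrix(0, n_img, 2)
  fallback <- character(n_img)
  pm <- projection_matrices(sol1$geometry)
  for (i in seq_len(n_img)) {
    sel <- which(base$image == i)
    used <- NA_character_
    if (length(sel)) {
      bfull <- monomial_basis(degree, z_degree,
                              rnorm_[as.character(base$marker[sel]), ,
                                     drop = FALSE])
      rhs <- c(base$ru[sel], base$rv[sel])
      for (nm_step in names(steps)) {
        mk <- steps[[nm_step]]
        ne_mask <- sum(mk)
        ne <- ne_mask * ncomp_effective(form) + if (refit_shifts) 2L else 0L
        if (2L * length(sel) >= ne || nm_step == "none") {
          used <- nm_step
          if (ne_mask > 0 || refit_shifts) {
            be <- bfull[, mk, drop = FALSE]
            if (form == "2d") {
              zer <- matrix(0, length(sel), ncol(be))
              dsg <- rbind(cbind(be, zer), cbind(zer, be))
            } else {
              # columns ordered (term 1: dx dy dz, term 2: dx dy dz, ...);
              # each column is the projected contribution of one 3D
              # coefficient to the stacked (u, v) residuals
              m <- pm[[i]]
              cols <- list()
              for (t in seq_len(ncol(be))) {
                for (axs in 1:3) {
                  cols[[length(cols) + 1L]] <-
                    c(be[, t] * m[1, axs], be[, t] * m[2, axs])
                }
              }
              dsg <- do.call(cbind, cols)
            }
            if (refit_shifts) {
              ones <- rep(1, length(sel)); zers <- rep(0, length(sel))
              dsg <- cbind(dsg, c(ones, zers), c(zers, ones))
            }
            x <- solve_minnorm(dsg, rhs)
            ncoef <- ne_mask * ncomp_effective(form)
            if (ncoef > 0) {
              cc <- matrix(x[seq_len(ncoef)],
                           nrow = ne_mask,
                           ncol = ncomp_effective(form),
                           byrow = (form == "3d"))
              full <- matrix(0, nc, ncomp)
              full[mk, ] <- cc
              # undo the coordinate normalisation
              pw <- tt$m + tt$n + tt$l
              coefs[[i]] <- full / scale^pw
            }
            if (refit_shifts) dshift[i, ] <- utils::tail(x, 2)
          }
          break
        }
      }
    } else {
      used <- "none"
    }
    fallback[i] <- used
  }
  motion <- motion_model(form, degree, z_degree, coefficients = coefs,
                         mask = steps$requested | !steps$requested,
                         mask_kind = mask_kind)
  geom <- sol1$geometry
  if (refit_shifts) {
    geom$du <- geom$du + dshift[, 1]
    geom$dv <- geom$dv + dshift[, 2]
  }
  sol <- alignment_solution(sol1$markers, geom, motion, tracks,
                            fit = c(sol1$fit,
                                    list(step1_mean_residual =
                                           mean(base$resid),
                                         fallback = fallback,
                                         scale = scale)))
  if (any(fallback != "requested"))
    message(sprintf("motion fit fell back on %d image(s): %s",
                    sum(fallback != "requested"),
                    paste(unique(fallback[fallback != "requested"]),
                          collapse = ", ")))
  sol
}

ncomp_effective <- function(form) if (form == "3d") 3L else 2L

#' Mean residual as a function of acquisition order
#'
#' Averages the per-observation residual norm of a fitted solution per
#' acquired image, in acquisition order. With dose-decaying beam-induced
#' motion and a motion-blind fit this curve is highest for the first images
#' of each branch and decays to a plateau; a motion-aware fit flattens it.
#'
#' @param sol a `tilt_alignment` with residuals.
#' @return A tibble with columns `acq_index`, `image`, `branch`, `tilt_deg`,
#'   `mean_residual`, `n_obs`, ordered by `acq_index`.
#' @export
residual_vs_acquisition <- function(sol) {
  stopifnot(inherits(sol, "tilt_alignment"), !is.null(sol$residuals))
  g <- sol$geometry[c("image", "acq_index", "branch", "tilt_deg")]
  res <- dplyr::summarise(dplyr::group_by(sol$residuals, .data$image),
                          mean_residual = mean(.data$resid),
                          n_obs = dplyr::n(), .groups = "drop")
  out <- dplyr::inner_join(g, res, by = "image")
  dplyr::arrange(out, .data$acq_index)
}

#' Ratio of measurements to motion unknowns
#'
#' Each observed fiducial contributes two measurements (u and v) per image;
#' the 2D motion model costs `2 * (enabled terms)` parameters per image.
#' Reported per image and averaged over the series. Images with zero enabled
#' parameters report an infinite ratio.
#'
#' @param tracks a [marker_tracks()] table.
#' @inheritParams fit_motion
#' @param n_images number of images in the series (defaults to the largest
#'   image index in `tracks`).
#' @return A list with `per_image` (tibble `image`, `n_obs`, `n_params`,
#'   `ratio`) and `average` (mean ratio over images with observations).
#' @export
measurements_to_unknowns_ratio <- function(tracks, degree = 2, z_degree = 0,
                                           mask_kind = "full",
                                           n_images = max(tracks$image)) {
  np <- per_image_param_count("2d", degree, z_degree,
                              term_mask(mask_kind, degree, z_degree))
  tab <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(tracks),
                                          .data$image),
                          n_obs = dplyr::n(), .groups = "drop")
  tab <- dplyr::left_join(tibble::tibble(image = seq_len(n_images)), tab,
                          by = "image")
  tab$n_obs[is.na(tab$n_obs)] <- 0L
  tab$n_params <- np
  tab$ratio <- if (np == 0) Inf else 2 * tab$n_obs / np
  list(per_image = tab,
       average = mean(tab$ratio[tab$n_obs > 0]))
}

#' Adopt an external (IMOD-style) alignment as the step-1 solution
#'
#' Builds a `tilt_alignment` from a `.tlt` tilt-angle file, an `.xf`
#' in-plane transform file and a table of 3D marker coordinates, without any
#' optimisation. The `.xf` rotation block is decomposed into an in-plane
#' rotation `psi` and an isotropic magnification.
#'
#' @param tlt_path path to a `.tlt` file (one angle in degrees per line).
#' @param xf_path path to an `.xf` file, or `NULL` for identity transforms.
#' @param markers tibble with columns `marker, x, y, z`.
#' @param tracks optional [marker_tracks()] to compute residuals against.
#' @param negate_tilt negate tilt angles on import (see [read_tlt()]).
#' @return A `tilt_alignment` (motion absent).
#' @export
import_external_alignment <- function(tlt_path, xf_path = NULL, markers,
                                      tracks = NULL, negate_tilt = FALSE) {
  tilt <- read_tlt(tlt_path, negate = negate_tilt)
  n <- length(tilt)
  psi <- rep(0, n); mag <- rep(1, n); du <- rep(0, n); dv <- rep(0, n)
  if (!is.null(xf_path)) {
    xf <- read_xf(xf_path)
    if (nrow(xf) != n)
      stop(sprintf(".tlt has %d images but .xf has %d lines", n, nrow(xf)),
           call. = FALSE)
    psi <- atan2(xf$a21 - xf$a12, xf$a11 + xf$a22) * 180 / pi
    mag <- sqrt(pmax(xf$a11 * xf$a22 - xf$a12 * xf$a21, 0))
    du <- xf$dx; dv <- xf$dy
  }
  geom <- tilt_geometry(tilt, psi_deg = psi, mag = mag, du = du, dv = dv)
  alignment_solution(markers, geom, motion = NULL, tracks = tracks,
                     fit = list(method = "external"))
}

#' Export / import an alignment solution as plain text
#'
#' One human-readable text file holding the per-image geometry table and
#' the fitted 3D marker coordinates. The motion model is serialised
#' separately with [write_motion_model()].
#'
#' @param sol a `tilt_alignment`.
#' @param path file path.
#' @return `write_alignment` returns `path` invisibly; `read_alignment`
#'   returns a `tilt_alignment` (without residuals).
#' @export
write_alignment <- function(sol, path) {
  g <- as.data.frame(sol$geometry)
  m <- as.data.frame(sol$markers)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# tiltmotion alignment v1", con)
  writeLines(sprintf("n_images %d", nrow(g)), con)
  writeLines(sprintf("n_markers %d", nrow(m)), con)
  writeLines("[geometry]", con)
  utils::write.table(format(g, digits = 17), con, quote = FALSE,
                     row.names = FALSE)
  writeLines("[markers]", con)
  utils::write.table(format(m, digits = 17), con, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_alignment
#' @export
read_alignment <- function(path) {
  ln <- readLines(path)
  gi <- which(ln == "[geometry]"); mi <- which(ln == "[markers]")
  if (!length(gi) || !length(mi))
    stop("not a tiltmotion alignment file", call. = FALSE)
  g <- utils::read.table(text = ln[(gi + 1):(mi - 1)], header = TRUE)
  m <- utils::read.table(text = ln[(mi + 1):length(ln)], header = TRUE)
  geom <- tilt_geometry(g$tilt_deg, psi_deg = g$psi_deg,
                        alpha_deg = g$alpha_deg, mag = g$mag,
                        du = g$du, dv = g$dv, acq_index = g$acq_index,
                        branch = g$branch)
  alignment_solution(tibble::as_tibble(m), geom,
                     fit = list(method = "imported"))
}

#' Plain-text alignment report
#'
#' Writes a summary block in the style of a per-tilt-series results table:
#' mean residual, measurement/unknown ratio, optional LOO residual, and the
#' per-acquisition residual curve.
#'
#' @param sol a fitted `tilt_alignment`.
#' @param path file path.
#' @param loo optional [loo_residual()] report to append.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(sol, path, loo = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# tiltmotion alignment report", con)
  writeLines(sprintf("n_markers %d", nrow(sol$markers)), con)
  writeLines(sprintf("n_images %d", nrow(sol$geometry)), con)
  writeLines(sprintf("motion %s", if (is.null(sol$motion)) "none"
                     else sprintf("%s D=%d Dz=%d mask=%s", sol$motion$form,
                                  sol$motion$degree, sol$motion$z_degree,
                                  sol$motion$mask_kind)), con)
  writeLines(sprintf("mean_residual %.6f", sol$mean_residual), con)
  if (!is.null(sol$fit$step1_mean_residual))
    writeLines(sprintf("standard_mean_residual %.6f",
                       sol$fit$step1_mean_residual), con)
  if (!is.null(loo)) {
    writeLines(sprintf("loo_residual %.6f", loo$loo_residual), con)
    writeLines(sprintf("loo_verdict %s",
                       if (loo$verdict) "model_validated" else
                         "possible_overfit"), con)
  }
  writeLines("[residual_vs_acquisition]", con)
  utils::write.table(as.data.frame(residual_vs_acquisition(sol)), con,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
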