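#' Define a synthetic doming tilt-series scenario
#'
#' Builds a ground-truthed scenario emulating beam-induced sample doming
#' over a two-branch tilt acquisition: gold-bead-like markers uniformly
#' placed in a slab, a per-image true motion model whose amplitude decays
#' exponentially with accumulated dose to a plateau, per-image random image
#' shifts, and Gaussian marker-localisation noise. All randomness comes
#' from one seeded generator; the same seed reproduces the scenario
#' byte-for-byte.
#'
#' The default acquisition mirrors a dose-symmetric-style collection of a
#' thin specimen: tilt range +/-60 deg at 3 deg increment, recorded in two
#' branches starting at -21 deg (first branch sweeping up to +60, second
#' from -24 down to -60), 41 images, 60 e-/A^2 total dose. The dome
#' amplitude decays from 18 px towards a 6.5 px plateau with dose constant
#' `tau = 12 / log(2)` e-/A^2 — the motion amplitude halves by ~12 e-/A^2
#' of accumulated exposure, after which the residual curve of a
#' motion-blind alignment plateaus. The amplitude scale is calibrated so
#' that a standard (motion-blind) alignment of the default scenario lands
#' in the mean-residual regime reported for real thin-specimen tilt-series
#' (standard alignment near 1.8-2 px, motion-aware fit near 0.7 px).
#'
#' @param n_markers number of fiducial markers.
#' @param fov field-of-view extent in pixels (markers span
#'   `[-fov/2, fov/2]` in x and y).
#' @param thickness slab thickness in pixels (marker z range).
#' @param tilt_min,tilt_max,tilt_step tilt scheme in degrees.
#' @param branch_start starting angle of the two acquisition branches.
#' @param amplitude0 dome amplitude at zero dose (pixels).
#' @param amplitude_plateau asymptotic amplitude (pixels).
#' @param tau dose constant of the exponential decay (e-/A^2).
#' @param total_dose accumulated exposure over the series (e-/A^2).
#' @param noise_sigma marker localisation noise s.d. (pixels).
#' @param shift_sigma s.d. of the true random per-image shifts (pixels).
#' @param shape_jitter relative per-image variation of the dome shape: each
#'   image's surface coefficients are `A_i * (base + shape_jitter *
#'   jitter_i)` with `jitter_i` drawn per image at the rms scale of the
#'   base shape. Beam-induced deformation is not a rescaled copy of one
#'   master surface — each exposure domes the ice differently, which is
#'   why the alignment models every image independently; 0 gives the
#'   rescaled-copy idealisation.
#' @param motion_form `"2d"` generates the true motion directly as
#'   image-plane surfaces (what the alignment can identify); `"3d"`
#'   generates a sample-frame dome triad (in-plane spread plus a z-dome)
#'   and stores it in 3D form, exercising the 2D/3D conversion and the
#'   beam-parallel unobservability.
#' @param degree,z_degree degree of the true surfaces.
#' @param seed integer seed.
#' @return An object of class `doming_scenario`.
#' @export
make_scenario <- function(n_markers = 40, fov = 512, thickness = 150,
                          tilt_min = -60, tilt_max = 60, tilt_step = 3,
                          branch_start = -21, amplitude0 = 18,
                          amplitude_plateau = 6.5, tau = 12 / log(2),
                          total_dose = 60, noise_sigma = 0.5,
                          shift_sigma = 2, shape_jitter = 0.5,
                          motion_form = c("2d", "3d"),
                          degree = 2, z_degree = 0, seed = 1) {
  motion_form <- match.arg(motion_form)
  if (tilt_step <= 0 || tilt_max <= tilt_min)
    stop("invalid tilt scheme", call. = FALSE)
  if (branch_start < tilt_min || branch_start > tilt_max)
    stop("branch_start must lie inside the tilt range", call. = FALSE)
  if (amplitude0 < 0 || amplitude_plateau < 0 || tau <= 0)
    stop("invalid amplitude schedule", call. = FALSE)
  branch1 <- seq(branch_start, tilt_max, by = tilt_step)
  branch2 <- if (branch_start - tilt_step >= tilt_min)
    seq(branch_start - tilt_step, tilt_min, by = -tilt_step) else numeric(0)
  acq_angles <- c(branch1, branch2)
  branch_of <- c(rep(1L, length(branch1)), rep(2L, length(branch2)))
  n <- length(acq_angles)
  stack_angles <- sort(acq_angles)
  # storage is in stack (angle) order; acq_index maps each stack image to
  # its acquisition rank
  acq_index <- match(stack_angles, acq_angles)
  withr::with_seed(seed, {
    mk <- tibble::tibble(
      marker = sprintf("m%02d", seq_len(n_markers)),
      x = stats::runif(n_markers, -fov / 2, fov / 2),
      y = stats::runif(n_markers, -fov / 2, fov / 2),
      z = stats::runif(n_markers, -thickness / 2, thickness / 2)
    )
    # enforce the sample-frame origin at the marker centroid
    mk$x <- mk$x - mean(mk$x); mk$y <- mk$y - mean(mk$y)
    mk$z <- mk$z - mean(mk$z)
    du <- stats::rnorm(n, 0, shift_sigma)
    dv <- stats::rnorm(n, 0, shift_sigma)
    shape <- doming_shapes(motion_form, degree, z_degree)
    # per-image shape variation (see argument docs); constants stay zero
    jit <- shape != 0
    s0 <- sqrt(mean(shape[jit]^2))
    shapes <- lapply(seq_len(n), function(i) {
      sh <- shape
      if (shape_jitter > 0 && any(jit))
        sh[jit] <- sh[jit] + stats::rnorm(sum(jit), 0, shape_jitter * s0)
      sh
    })
  })
  geom <- tilt_geometry(stack_angles, du = du, dv = dv,
                        acq_index = acq_index,
                        branch = branch_of[acq_index])
  dose_per_image <- total_dose / n
  dose_before <- (geom$acq_index - 1) * dose_per_image
  amp <- amplitude_plateau +
    (amplitude0 - amplitude_plateau) * exp(-dose_before / tau)
  rad <- fov / 2
  tt <- poly_terms(degree, z_degree)
  pw <- tt$m + tt$n + tt$l
  zscale <- max(thickness / 2, 1)
  coefs <- lapply(seq_len(n), function(i) {
    cc <- shapes[[i]] * amp[i]
    # shapes are defined on coordinates normalised by the field radius
    # (and half-thickness in z); rescale to raw pixel coordinates
    sc <- rad^(tt$m + tt$n) * zscale^tt$l
    cc / sc
  })
  motion_true <- motion_model(motion_form, degree, z_degree,
                              coefficients = coefs)
  if (motion_form == "3d") {
    motion_2d_true <- convert_3d_to_2d(motion_true, geom)
  } else {
    motion_2d_true <- motion_true
  }
  structure(list(geometry = geom, markers = mk, motion_true = motion_true,
                 motion_2d_true = motion_2d_true, amplitudes = amp,
                 noise_sigma = noise_sigma, fov = fov,
                 thickness = thickness, dose_per_image = dose_per_image,
                 seed = seed, degree = degree, z_degree = z_degree,
                 motion_form = motion_form),
            class = "doming_scenario")
}

# fixed unit-amplitude dome shapes on normalised coordinates.
# 2d form: image-plane surfaces of a dome seen in projection — dominated by
# the quadratic bowl, with mild linear spreading; constants are zero (a
# global shift belongs to d_i).
# 3d form: radial in-plane spreading plus a z-dome 1 - (x^2 + y^2).
doming_shapes <- function(form, degree, z_degree) {
  tt <- poly_terms(degree, z_degree)
  pick <- function(lbls, vals) {
    out <- numeric(nrow(tt))
    idx <- match(lbls, tt$label)
    out[idx[!is.na(idx)]] <- vals[!is.na(idx)]
    out
  }
  if (form == "2d") {
    su <- pick(c("P100", "P010", "P200", "P110", "P020", "P001"),
               c(0.15, -0.10, -0.55, 0.20, -0.35, 0.25))
    sv <- pick(c("P100", "P010", "P200", "P110", "P020", "P001"),
               c(-0.08, 0.12, -0.30, -0.15, -0.50, -0.20))
    cbind(su = su, sv = sv)
  } else {
    dx <- pick(c("P100"), c(0.25))
    dy <- pick(c("P010"), c(0.25))
    dz <- pick(c("P000", "P200", "P020"), c(0, -1, -1))
    cbind(dx = dx, dy = dy, dz = dz)
  }
}

#' @export
print.doming_scenario <- function(x, ...) {
  cat(sprintf(
    "<doming_scenario> %d markers, %d images, %s motion D=%d Dz=%d, A0=%.3g px, sigma=%.3g px, seed=%d\n",
    nrow(x$markers), nrow(x$geometry), x$motion_form, x$degree, x$z_degree,
    max(x$amplitudes), x$noise_sigma, x$seed))
  invisible(x)
}

#' Simulate marker tracks from a doming scenario
#'
#' Generates measured fiducial positions `q_ji = M_i r_j + S_i(r_j) + d_i +
#' noise` from the scenario's true geometry and motion. The truth bundle
#' (markers, geometry, true motion in both forms) accompanies the tracks
#' for recovery tests.
#'
#' @param scenario a [make_scenario()] object.
#' @param dropout fraction of (marker, image) observations randomly removed
#'   (missing observations).
#' @param seed_offset added to the scenario seed for the noise stream, so
#'   several noise realisations of one scenario can be drawn.
#' @return A list with `tracks` (a [marker_tracks()] tibble) and `truth`
#'   (list `markers`, `geometry`, `motion`, `motion_2d`, `noise_sigma`).
#' @export
simulate_tracks <- function(scenario, dropout = 0, seed_offset = 0) {
  stopifnot(inherits(scenario, "doming_scenario"))
  mk <- scenario$markers
  geom <- scenario$geometry
  pairs <- tidyr::expand_grid(marker = mk$marker,
                              image = seq_len(nrow(geom)))
  pred <- predict_pairs(mk, geom, scenario$motion_2d_true, pairs)
  withr::with_seed(scenario$seed + 7919L * (seed_offset + 1L), {
    nobs <- nrow(pred)
    pred$u <- pred$u + stats::rnorm(nobs, 0, scenario$noise_sigma)
    pred$v <- pred$v + stats::rnorm(nobs, 0, scenario$noise_sigma)
    keep <- if (dropout > 0) stats::runif(nobs) >= dropout else
      rep(TRUE, nobs)
  })
  tracks <- marker_tracks(pred[keep, ])
  list(tracks = tracks,
       truth = list(markers = mk, geometry = geom,
                    motion = scenario$motion_true,
                    motion_2d = scenario$motion_2d_true,
                    noise_sigma = scenario$noise_sigma))
}

#' Step-1 solution from a scenario's ground truth
#'
#' Packs the true marker coordinates and image parameters of a scenario
#' into a `tilt_alignment`, as when adopting an external alignment. Useful
#' as the reference for noise-free motion-recovery tests.
#'
#' @param scenario a [make_scenario()] object.
#' @param tracks optional tracks to attach residuals.
#' @return A `tilt_alignment` (motion absent).
#' @export
truth_alignment <- function(scenario, tracks = NULL) {
  alignment_solution(scenario$markers, scenario$geometry, motion = NULL,
                     tracks = tracks, fit = list(method = "truth"))
}

#' Render a synthetic tilt-series stack
#'
#' Renders projection images of the scenario's phantom under the true
#' motion: each bead (or point) is drawn as a Gaussian blob at its tracked,
#' motion-displaced projected position. Optional white noise. Paired with
#' [simulate_tracks()] truth for reconstruction tests.
#'
#' @param scenario a [make_scenario()] object.
#' @param content `"beads"` (blobs at the scenario markers), `"points"`
#'   (single central point source) or `"two_spheres"` (two off-centre
#'   blobs).
#' @param nx,ny image size in pixels.
#' @param bead_sigma Gaussian blob s.d. in pixels.
#' @param noise_sd white-noise s.d. added to every pixel.
#' @param use_motion render with the true motion (otherwise motion-free
#'   projections).
#' @return A list with `stack` (`nx x ny x N` array), `positions` (the 3D
#'   phantom positions) and `scenario`.
#' @export
render_stack <- function(scenario, content = c("beads", "points",
                                               "two_spheres"),
                         nx = 256, ny = 256, bead_sigma = 2, noise_sd = 0,
                         use_motion = TRUE) {
  content <- match.arg(content)
  stopifnot(inherits(scenario, "doming_scenario"))
  pos <- switch(content,
    beads = as.matrix(scenario$markers[c("x", "y", "z")]),
    points = matrix(c(0, 0, 0), 1, 3),
    two_spheres = rbind(c(-scenario$fov / 8, 0, scenario$thickness / 4),
                        c(scenario$fov / 8, 0, -scenario$thickness / 4)))
  geom <- scenario$geometry
  sol <- alignment_solution(
    tibble::tibble(marker = sprintf("p%d", seq_len(nrow(pos))),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3]),
    geom, motion = if (use_motion) scenario$motion_2d_true else NULL)
  nimg <- nrow(geom)
  stack <- array(0, c(nx, ny, nimg))
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  w <- ceiling(4 * bead_sigma)
  for (i in seq_len(nimg)) {
    uv <- project_points_one(pos, sol, i)
    img <- matrix(0, nx, ny)
    for (k in seq_len(nrow(uv))) {
      pu <- uv[k, 1] + cx; pv <- uv[k, 2] + cy
      if (pu + w < 1 || pu - w > nx || pv + w < 1 || pv - w > ny) next
      us <- max(1, floor(pu - w)):min(nx, ceiling(pu + w))
      vs <- max(1, floor(pv - w)):min(ny, ceiling(pv + w))
      gu <- exp(-((us - pu)^2) / (2 * bead_sigma^2))
      gv <- exp(-((vs - pv)^2) / (2 * bead_sigma^2))
      img[us, vs] <- img[us, vs] + outer(gu, gv)
    }
    stack[, , i] <- img
  }
  if (noise_sd > 0) {
    withr::with_seed(scenario$seed + 104729L, {
      stack <- stack + array(stats::rnorm(length(stack), 0, noise_sd),
                             dim(stack))
    })
  }
  list(stack = stack, positions = pos, scenario = scenario)
}

#' Write every artefact of a scenario to a directory
#'
#' Emits the files a command-line run consumes: the marker-track table, the
#' `.tlt` tilt-angle file, the true motion model in the text format, the
#' truth alignment, and optionally a rendered MRC stack.
#'
#' @param scenario a [make_scenario()] object.
#' @param dir output directory (created if needed).
#' @param stack also render and write a bead stack (`stack.mrc`).
#' @param nx,ny stack size when `stack = TRUE`.
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir, stack = FALSE, nx = 256,
                           ny = 256) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_tracks(scenario)
  write_tracks(sim$tracks, file.path(dir, "tracks.txt"))
  write_tlt(scenario$geometry$tilt_deg, file.path(dir, "angles.tlt"))
  write_motion_model(scenario$motion_2d_true,
                     file.path(dir, "motion_true.txt"))
  write_alignment(truth_alignment(scenario),
                  file.path(dir, "alignment_true.txt"))
  writeLines(sprintf("seed %d", scenario$seed),
             file.path(dir, "scenario_seed.txt"))
  if (stack) {
    rs <- render_stack(scenario, nx = nx, ny = ny)
    write_mrc(rs$stack, file.path(dir, "stack.mrc"))
  }
  invisible(dir)
}
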