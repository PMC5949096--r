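test_that("predict_positions applies p = M r + S(r) + d", {
  geom <- tilt_geometry(0)
  mk <- tibble::tibble(marker = "a", x = 1, y = 2, z = 3)
  trk <- marker_tracks(tibble::tibble(marker = "a", image = 1, u = 1, v = 2),
                       min_obs = 1)
  sol <- alignment_solution(mk, geom, tracks = trk)
  expect_equal(as.numeric(predict_positions(sol)[1, c("u", "v")]), c(1, 2))
  # constant Su = 0.5 through an enabled constant term
  co <- matrix(0, 6, 2); co[1, 1] <- 0.5
  sol$motion <- motion_model("2d", 2, 0, coefficients = list(co))
  expect_equal(as.numeric(predict_positions(sol)[1, c("u", "v")]),
               c(1.5, 2))
  # randomized: 2D predictions equal the 3D-form route (projection of the
  # sample-frame motion)
  geomr <- tilt_geometry(c(-40, 10, 55), psi_deg = 3, du = 1, dv = -2)
  m3 <- random_motion_3d(geomr, seed = 9, scale = 0.02)
  withr::with_seed(10, mks <- tibble::tibble(
    marker = letters[1:6], x = rnorm(6, 0, 50), y = rnorm(6, 0, 50),
    z = rnorm(6, 0, 20)))
  pairs <- tidyr::expand_grid(marker = mks$marker, image = 1:3)
  trk <- marker_tracks(dplyr::mutate(pairs, u = 0, v = 0))
  s3 <- alignment_solution(mks, geomr, motion = m3, tracks = trk)
  s2 <- alignment_solution(mks, geomr,
                           motion = convert_3d_to_2d(m3, geomr),
                           tracks = trk)
  expect_equal(predict_positions(s3)$u, predict_positions(s2)$u,
               tolerance = 1e-10)
  expect_equal(predict_positions(s3)$v, predict_positions(s2)$v,
               tolerance = 1e-10)
})

test_that("objective is the naive sum of squared residual distances", {
  sc <- small_scenario(seed = 4)
  sim <- simulate_tracks(sc)
  sol <- truth_alignment(sc, sim$tracks)
  # brute-force double loop oracle
  f <- 0
  for (k in seq_len(nrow(sim$tracks))) {
    ob <- sim$tracks[k, ]
    g <- sc$geometry[ob$image, ]
    r <- as.numeric(sc$markers[sc$markers$marker == ob$marker,
                               c("x", "y", "z")])
    p <- unname(project_marker(g, r) +
      drop(eval_motion(sc$motion_2d_true, ob$image, matrix(r, 1))))
    f <- f + (ob$u - p[1])^2 + (ob$v - p[2])^2
  }
  sol$motion <- sc$motion_2d_true
  expect_equal(objective(sol, sim$tracks), f, tolerance = 1e-10)
  # exact fit gives zero; a single (3,4) offset gives 25
  sc0 <- small_scenario(seed = 5, noise_sigma = 0, amplitude0 = 0,
                        amplitude_plateau = 0)
  sim0 <- simulate_tracks(sc0)
  sol0 <- truth_alignment(sc0, sim0$tracks)
  expect_equal(objective(sol0, sim0$tracks), 0, tolerance = 1e-16)
  t1 <- sim0$tracks
  t1$u[1] <- t1$u[1] + 3; t1$v[1] <- t1$v[1] + 4
  expect_equal(objective(sol0, t1), 25, tolerance = 1e-10)
})

test_that("standard_align recovers noise-free motion-free truth exactly", {
  sc <- make_scenario(n_markers = 15, noise_sigma = 0, amplitude0 = 0,
                      amplitude_plateau = 0, seed = 8)
  sim <- simulate_tracks(sc)
  sol <- standard_align(sim$tracks, initial_geometry(sc))
  expect_lt(sol$mean_residual, 1e-6)
  # truth centroid is at the origin, so the gauge-fixed solution matches it
  got <- dplyr::arrange(sol$markers, .data$marker)
  want <- dplyr::arrange(sc$markers, .data$marker)
  expect_equal(got$x, want$x, tolerance = 1e-6)
  expect_equal(got$y, want$y, tolerance = 1e-6)
  expect_equal(got$z, want$z, tolerance = 1e-6)
  expect_equal(sol$geometry$du, sc$geometry$du, tolerance = 1e-6)
})

test_that("standard_align residual matches least-squares degrees of freedom", {
  # rms residual per measurement ~ sigma * sqrt(1 - p/n)
  sc <- make_scenario(n_markers = 30, noise_sigma = 1, amplitude0 = 0,
                      amplitude_plateau = 0, seed = 12)
  sim <- simulate_tracks(sc)
  sol <- standard_align(sim$tracks, initial_geometry(sc))
  n <- 2 * nrow(sim$tracks)
  p <- 3 * 30 + 2 * nrow(sc$geometry) - 3
  expect_equal(sqrt(sol$objective / n), 1 * sqrt(1 - p / n),
               tolerance = 0.2)
})

test_that("under-determined alignment fails with an explicit deficit", {
  trk <- marker_tracks(tibble::tibble(marker = "a", image = c(1, 2),
                                      u = c(0, 1), v = c(0, 1)),
                       min_obs = 1)
  expect_error(standard_align(trk, tilt_geometry(c(0, 30))),
               "under-determined")
})

test_that("per-image refinement of rotation/tilt/magnification works", {
  sc <- make_scenario(n_markers = 15, noise_sigma = 0, amplitude0 = 0,
                      amplitude_plateau = 0, seed = 21)
  sim <- simulate_tracks(sc)
  # perturb the assumed in-plane rotations; plain step 1 cannot fit them
  geom_bad <- initial_geometry(sc)
  geom_bad$psi_deg <- geom_bad$psi_deg + 0.3
  ref_img <- which.min(abs(geom_bad$tilt_deg))
  geom_bad$psi_deg[ref_img] <- 0  # reference image is correct
  plain <- standard_align(sim$tracks, geom_bad)
  refined <- standard_align(sim$tracks, geom_bad, refine = "rotation")
  expect_lt(refined$mean_residual, plain$mean_residual / 5)
  expect_lt(refined$mean_residual, 1e-4)
  expect_equal(refined$geometry$psi_deg[-ref_img],
               rep(0, nrow(geom_bad) - 1), tolerance = 1e-3)
})

test_that("motion fit recovers known coefficients from noise-free doming", {
  sc <- make_scenario(noise_sigma = 0, seed = 31)
  sim <- simulate_tracks(sc)
  sol1 <- truth_alignment(sc, sim$tracks)
  fit <- fit_motion(sol1, sim$tracks)
  expect_lt(fit$mean_residual, 1e-6)
  err <- max(mapply(function(a, b) max(abs(a - b)),
                    fit$motion$coefficients,
                    sc$motion_2d_true$coefficients))
  expect_lt(err, 1e-6)
})

test_that("motion fit never increases the mean residual", {
  for (s in 1:5) {
    sc <- small_scenario(seed = s)
    sim <- simulate_tracks(sc, dropout = 0.1)
    sol1 <- standard_align(sim$tracks, initial_geometry(sc))
    fit <- suppressMessages(fit_motion(sol1, sim$tracks))
    expect_lte(fit$mean_residual, sol1$mean_residual + 1e-12)
    # trivariate never beats itself worse either
    fit3 <- suppressMessages(fit_motion(sol1, sim$tracks, z_degree = 2))
    expect_lte(fit3$mean_residual, sol1$mean_residual + 1e-12)
  }
})

test_that("scarce markers trigger the documented fallback ladder", {
  sc <- make_scenario(n_markers = 3, seed = 14)
  sim <- simulate_tracks(sc)
  sol1 <- truth_alignment(sc, sim$tracks)
  expect_message(fit <- fit_motion(sol1, sim$tracks), "fell back")
  # 3 markers give 6 measurements: too few for 10 gauge-masked bivariate
  # terms, enough for the 4 pure linear+quadratic pure terms
  expect_true(all(fit$fit$fallback %in% c("pure_terms", "linear", "none")))
  expect_lte(fit$mean_residual,
             tiltmotion:::residual_table(sol1$markers, sol1$geometry, NULL,
                                         sim$tracks)$resid |> mean())
})

test_that("2D and 3D motion fits are equivalent and beam-blind", {
  sc <- small_scenario(seed = 17)
  sim <- simulate_tracks(sc)
  sol1 <- standard_align(sim$tracks, initial_geometry(sc))
  f2 <- fit_motion(sol1, sim$tracks)
  f3 <- fit_motion_3d(sol1, sim$tracks)
  expect_lt(max(abs(f2$residuals$resid - f3$residuals$resid)), 1e-8)
  # theta = 0 image: the beam is the z-axis, so dz is unidentifiable and
  # minimum-norm leaves it at zero
  i0 <- which(sc$geometry$tilt_deg == 0)
  expect_equal(f3$motion$coefficients[[i0]][, "dz"],
               rep(0, 6), tolerance = 1e-10, ignore_attr = TRUE)
  # fitted 3D shifts are perpendicular to the beam in every image
  withr::with_seed(2, pts <- matrix(rnorm(300, 0, 150), 100, 3))
  for (i in seq_len(nrow(sc$geometry))) {
    beam <- tiltmotion:::beam_direction(sc$geometry[i, ])
    comp <- eval_motion(f3$motion, i, pts) %*% beam
    expect_lt(max(abs(comp)), 1e-8)
  }
})

test_that("residual-vs-acquisition summarises per acquired image", {
  sc <- small_scenario(seed = 3, noise_sigma = 0, amplitude0 = 0,
                       amplitude_plateau = 0)
  sim <- simulate_tracks(sc)
  # offset every measured u by 1 px: every residual norm is exactly 1
  t1 <- sim$tracks
  t1$u <- t1$u + 1
  sol <- truth_alignment(sc, t1)
  rv <- residual_vs_acquisition(sol)
  expect_equal(rv$mean_residual, rep(1, nrow(sc$geometry)))
  expect_identical(rv$acq_index, seq_len(nrow(sc$geometry)))
  # with dose-decaying doming the first acquired image dominates the last
  sc2 <- make_scenario(seed = 23)
  sim2 <- simulate_tracks(sc2)
  s1 <- standard_align(sim2$tracks, initial_geometry(sc2))
  rv1 <- residual_vs_acquisition(s1)
  expect_gt(rv1$mean_residual[rv1$acq_index == 1],
            rv1$mean_residual[rv1$acq_index == max(rv1$acq_index)])
})

test_that("measurements-to-unknowns ratio follows the 2D bookkeeping", {
  mk6 <- tidyr::expand_grid(marker = letters[1:6], image = 1:5)
  trk <- marker_tracks(dplyr::mutate(mk6, u = 0, v = 0))
  r6 <- measurements_to_unknowns_ratio(trk, 2, 0)
  expect_equal(r6$average, 1.0)        # 12 measurements / 12 parameters
  mk44 <- tidyr::expand_grid(marker = sprintf("m%02d", 1:44), image = 1:5)
  r44 <- measurements_to_unknowns_ratio(
    marker_tracks(dplyr::mutate(mk44, u = 0, v = 0)), 2, 0)
  expect_equal(r44$average, 88 / 12, tolerance = 1e-12)
  # images without observations still appear, with zero measurements
  r5 <- measurements_to_unknowns_ratio(trk, 2, 0, n_images = 7)
  expect_identical(nrow(r5$per_image), 7L)
  expect_equal(r5$per_image$ratio[6:7], c(0, 0))
})

test_that("external alignments can be adopted and round-tripped", {
  tdir <- withr::local_tempdir()
  tlt <- file.path(tdir, "a.tlt"); xf <- file.path(tdir, "a.xf")
  write_tlt(c(-10, 0, 10), tlt)
  # identity transforms
  write_xf(data.frame(a11 = 1, a12 = 0, a21 = 0, a22 = 1, dx = 0, dy = 0)[
    rep(1, 3), ], xf)
  mk <- tibble::tibble(marker = "a", x = 0, y = 0, z = 0)
  sol <- import_external_alignment(tlt, xf, mk)
  expect_equal(sol$geometry$psi_deg, rep(0, 3))
  expect_equal(sol$geometry$mag, rep(1, 3))
  expect_equal(sol$geometry$tilt_deg, c(-10, 0, 10))
  # a 10-degree in-plane rotation is recovered from the 2x2 block
  th <- 10 * pi / 180
  write_xf(data.frame(a11 = cos(th), a12 = -sin(th), a21 = sin(th),
                      a22 = cos(th), dx = 1.5, dy = -2)[rep(1, 3), ], xf)
  sol10 <- import_external_alignment(tlt, xf, mk)
  expect_equal(sol10$geometry$psi_deg, rep(10, 3), tolerance = 1e-6)
  expect_equal(sol10$geometry$du, rep(1.5, 3), tolerance = 1e-3)
  # full alignment round trip
  sc <- small_scenario(seed = 2)
  sim <- simulate_tracks(sc)
  s1 <- standard_align(sim$tracks, initial_geometry(sc))
  f <- file.path(tdir, "sol.txt")
  write_alignment(s1, f)
  back <- read_alignment(f)
  expect_equal(back$geometry$du, s1$geometry$du, tolerance = 1e-9)
  expect_equal(back$markers$x, s1$markers$x, tolerance = 1e-9)
})

test_that("tidy, glance and autoplot work on fitted objects", {
  sc <- small_scenario(seed = 6)
  sim <- simulate_tracks(sc)
  s1 <- standard_align(sim$tracks, initial_geometry(sc))
  td <- generics::tidy(s1)
  expect_true(all(c("marker", "image", "resid") %in% names(td)))
  gl <- generics::glance(s1)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$mean_residual, s1$mean_residual)
  p <- ggplot2::autoplot(s1)
  expect_s3_class(p, "ggplot")
  p2 <- plot_residual_curves(standard = s1)
  expect_s3_class(p2, "ggplot")
})
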