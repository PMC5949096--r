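test_that("track_position matches the fiducial projection model", {
  geom <- tilt_geometry(c(-30, 0, 30))
  mk <- tibble::tibble(marker = "a", x = 10, y = -5, z = 8)
  trk <- marker_tracks(tibble::tibble(marker = "a", image = 1:3,
                                      u = 0, v = 0))
  sol <- alignment_solution(mk, geom, tracks = trk)
  # zero motion, identity image: (x, y) in the untilted image
  t0 <- track_position(c(10, -5, 8), sol)
  expect_equal(c(t0$u[2], t0$v[2]), c(10, -5))
  # at a fitted fiducial, tracking equals predict_positions exactly
  pp <- predict_positions(sol)
  expect_equal(t0$u, pp$u)
  expect_equal(t0$v, pp$v)
  # 3D-form route agrees with the 2D-form route at a random point
  m3 <- random_motion_3d(geom, seed = 5, scale = 0.02)
  sol3 <- sol; sol3$motion <- m3
  sol2 <- sol; sol2$motion <- convert_3d_to_2d(m3, geom)
  x <- c(33.3, -21.0, 12.5)
  expect_equal(track_position(x, sol3)$u, track_position(x, sol2)$u,
               tolerance = 1e-10)
  expect_equal(track_position(x, sol3)$v, track_position(x, sol2)$v,
               tolerance = 1e-10)
})

test_that("ramp filter removes DC, is linear, matches a DFT oracle", {
  expect_equal(max(abs(ramp_filter(rep(3.2, 64)))), 0)
  withr::with_seed(8, {
    f <- rnorm(48); g <- rnorm(48)
  })
  expect_lt(max(abs(ramp_filter(2 * f - 3 * g) -
                      (2 * ramp_filter(f) - 3 * ramp_filter(g)))), 1e-10)
  # delta input against brute-force DFT evaluation of |omega| weighting
  n <- 32
  delta <- c(1, rep(0, n - 1))
  got <- ramp_filter(delta)
  k <- 0:(n - 1)
  freq <- c(0:(n / 2), -((n / 2 - 1):1)) / n
  dft <- exp(-2i * pi * outer(k, k) / n)
  oracle <- Re(Conj(dft) %*% (abs(freq) * (dft %*% delta))) / n
  expect_equal(got, drop(oracle), tolerance = 1e-10)
  # hamming apodisation tapers the highest frequency
  gh <- ramp_filter(delta, apodize = "hamming")
  expect_false(isTRUE(all.equal(gh, got)))
})

test_that("backprojection peaks at a point source (adjointness sanity)", {
  sc <- make_scenario(n_markers = 4, seed = 5, amplitude0 = 0,
                      amplitude_plateau = 0, shift_sigma = 0)
  rs <- render_stack(sc, content = "points", nx = 96, ny = 96,
                     bead_sigma = 1.5)
  sol <- truth_alignment(sc)
  vol <- reconstruct_wbp(rs$stack, sol, c(24, 24, 24), filter = FALSE)
  peak <- which(vol == max(vol), arr.ind = TRUE)
  # source at the origin: volume centre falls between voxels 12 and 13
  expect_true(all(peak >= 12 & peak <= 13))
})

test_that("zero motion model reproduces the standard reconstruction", {
  sc <- make_scenario(n_markers = 4, seed = 6)
  rs <- render_stack(sc, content = "two_spheres", nx = 96, ny = 96)
  sol <- truth_alignment(sc)
  sol$motion <- motion_model("2d", 2, 0, n_images = nrow(sc$geometry))
  va <- reconstruct_wbp(rs$stack, sol, c(20, 20, 12), use_motion = TRUE)
  vb <- reconstruct_wbp(rs$stack, sol, c(20, 20, 12), use_motion = FALSE)
  expect_lt(max(abs(va - vb)), 1e-8)
})

test_that("reconstruction is linear in the input stack", {
  sc <- make_scenario(n_markers = 4, seed = 7)
  rs <- render_stack(sc, content = "two_spheres", nx = 64, ny = 64)
  sol <- truth_alignment(sc)
  sol$motion <- sc$motion_2d_true
  withr::with_seed(9, noise <- array(rnorm(length(rs$stack)),
                                     dim(rs$stack)))
  shp <- c(16, 16, 8)
  v1 <- reconstruct_wbp(rs$stack, sol, shp)
  v2 <- reconstruct_wbp(noise, sol, shp)
  v12 <- reconstruct_wbp(rs$stack + 2 * noise, sol, shp)
  expect_lt(max(abs(v12 - (v1 + 2 * v2))), 1e-8)
})

test_that("stack/geometry mismatches are rejected", {
  sc <- make_scenario(n_markers = 4, seed = 8)
  sol <- truth_alignment(sc)
  bad <- array(0, c(32, 32, 5))
  expect_error(reconstruct_wbp(bad, sol, c(8, 8, 8)), "images")
})

test_that("subtiltseries are centred on the compensated particle", {
  sc <- make_scenario(n_markers = 8, seed = 3)
  rs <- render_stack(sc, content = "beads", nx = 256, ny = 256)
  sol <- truth_alignment(sc)
  sol$motion <- sc$motion_2d_true
  ctr <- as.numeric(sc$markers[1, c("x", "y", "z")])
  st <- extract_subtiltseries(rs$stack, sol, ctr, patch_px = 17)
  expect_s3_class(st, "subtiltseries")
  expect_gt(sum(st$table$present), 0)
  half <- 9  # centre pixel of a 17 px patch
  errs <- vapply(which(st$table$present), function(i) {
    p <- st$patches[, , i]
    if (sum(p) < 1e-8) return(NA_real_)
    w <- p / sum(p)
    cu <- sum(row(p) * w) - half
    cv <- sum(col(p) * w) - half
    sqrt((cu - st$table$offset_u[i])^2 + (cv - st$table$offset_v[i])^2)
  }, numeric(1))
  expect_lt(max(errs, na.rm = TRUE), 0.5)
  # zero motion, identity-geometry position at the origin: patches sit at
  # the image centre in every image
  sc0 <- make_scenario(n_markers = 4, seed = 4, amplitude0 = 0,
                       amplitude_plateau = 0, shift_sigma = 0)
  rs0 <- render_stack(sc0, content = "points", nx = 64, ny = 64)
  st0 <- extract_subtiltseries(rs0$stack, truth_alignment(sc0),
                               c(0, 0, 0), patch_px = 9)
  expect_true(all(st0$table$present))
  expect_equal(st0$table$u, rep(0, nrow(st0$table)))
  # a position projecting outside at high tilt is flagged absent there
  far <- extract_subtiltseries(rs0$stack, truth_alignment(sc0),
                               c(40, 0, 0), patch_px = 9)
  expect_false(all(far$table$present))
  expect_true(any(far$table$present))
})

test_that("MRC files round-trip data and pixel size", {
  tdir <- withr::local_tempdir()
  withr::with_seed(10, v <- array(rnorm(8 * 8 * 3), c(8, 8, 3)))
  f <- file.path(tdir, "v.mrc")
  write_mrc(v, f, voxel_size = 2.17)
  back <- read_mrc(f)
  expect_equal(back$data, v, tolerance = 1e-6)  # float32 storage
  expect_equal(back$voxel_size, 2.17, tolerance = 1e-6)
  # mode-1 (int16) input is promoted exactly
  con <- file(file.path(tdir, "i16.mrc"), "wb")
  writeBin(as.integer(c(4, 2, 1, 1, rep(0L, 3), 4L, 2L, 1L)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(4, 2, 1, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1, 2, 3)), con, size = 4, endian = "little")
  writeBin(raw(1024 - 19 * 4), con)
  writeBin(as.integer(c(-7, 0, 3, 32000, -32000, 12, 1, 2)), con, size = 2,
           endian = "little")
  close(con)
  m1 <- read_mrc(file.path(tdir, "i16.mrc"))
  expect_equal(as.numeric(m1$data), c(-7, 0, 3, 32000, -32000, 12, 1, 2))
  # truncated data is detected
  con <- file(file.path(tdir, "bad.mrc"), "wb")
  writeBin(as.integer(c(100, 100, 100, 2, rep(0L, 6))), con, size = 4,
           endian = "little")
  writeBin(raw(1024 - 40), con)
  writeBin(1.5, con, size = 4, endian = "little")
  close(con)
  expect_error(read_mrc(file.path(tdir, "bad.mrc")), "shorter")
})
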