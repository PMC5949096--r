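# shared fixtures: everything is generated in code at test time

# initial geometry as a user would supply it: tilt angles and acquisition
# bookkeeping known, shifts unknown
initial_geometry <- function(scenario) {
  tilt_geometry(scenario$geometry$tilt_deg,
                acq_index = scenario$geometry$acq_index,
                branch = scenario$geometry$branch)
}

# small, fast scenario for unit tests (fewer markers, default 41 images)
small_scenario <- function(seed = 1, ...) {
  make_scenario(n_markers = 12, seed = seed, ...)
}

# a random 3D-form quadratic motion model over a geometry
random_motion_3d <- function(geom, degree = 2, z_degree = 0, seed = 42,
                             scale = 1e-4) {
  nc <- count_coeffs(degree, z_degree)
  withr::with_seed(seed, {
    coefs <- lapply(seq_len(nrow(geom)), function(i)
      matrix(stats::rnorm(nc * 3, 0, scale), nc, 3))
  })
  motion_model("3d", degree, z_degree, coefficients = coefs)
}

expect_tilt_alignment <- function(sol) {
  expect_s3_class(sol, "tilt_alignment")
  expect_true(is.finite(sol$mean_residual))
}
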