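Package: tiltmotion
Title: Motion-Aware Fiducial Tilt-Series Alignment and Tomographic
    Reconstruction for Cryo-Electron Tomography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fiducial-based alignment of electron cryo-tomography
    tilt-series with explicit modelling of beam-induced sample motion.
    The drum-like doming of the vitreous-ice layer is represented by
    per-image quadratic polynomial surfaces, either as 3D shifts in the
    sample frame or, equivalently after projection, as 2D shifts at the
    image plane. Provides the standard projection model and bundle-style
    least-squares alignment, per-image linear fitting of the motion
    polynomials, leave-one-out cross-validation of the motion model,
    motion-compensated weighted backprojection, voxel tracking and
    subtiltseries extraction, readers and writers for IMOD-style text
    formats and MRC stacks, and a ground-truthed synthetic doming
    tilt-series generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
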