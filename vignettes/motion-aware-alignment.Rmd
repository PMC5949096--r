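---
title: "Motion-aware tilt-series alignment: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-aware tilt-series alignment: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltmotion)
```

## The projection model and its conventions

A single-tilt-axis series is described per image by the Euler rotation
`R_i = Rz(psi_i) Ry(theta_i) Rx(alpha_i)`, the beam-axis projection `P`
(drop the microscope Z row), an isotropic magnification `m_i` and a shift
`d_i`; a bead at `r_j` (pixels, sample frame) appears at
`p_ji = m_i P R_i r_j + d_i`. Conventions the package pins, because the
formats it reads do not:

* Right-handed axes; **positive tilt maps +X to −Z**, i.e.
  `Ry = [[c, 0, s], [0, 1, 0], [−s, 0, c]]`. Whether a given stack was
  recorded with this sign or its mirror is not recoverable from a `.tlt`
  file, so `read_tlt(negate = TRUE)` flips angles on import.
* The in-plane rotation `psi` is outermost: physically it acts on the
  recorded image, after projection, but commutes into `R_i`.
* Image coordinates `(u, v)` in pixels, origin at the image centre
  (`(size − 1)/2` in 0-based array indexing), `u` rightward, `v` upward.
* The sample origin sits at the centroid of the fitted fiducials.

## Motion surfaces

Per image, the displacement of the sample is a triad of polynomial
surfaces `D_i = (dx, dy, dz)` in the sample frame, or an exactly
equivalent pair `S_i = M_i D_i` at the image plane. Surfaces are
polynomials `sum P_mnl x^m y^n z^l` with `m + n ≤ D − l`, `l ≤ Dz`;
`Dz = 0` is the bivariate family (thin samples), `Dz = D` the trivariate
one (thick samples, where motion varies across the slab). Quadratics
(`D = 2`) suffice to describe doming geometrically. Coefficient order is
pinned as: z-power ascending, then total xy-degree, then x-power
descending (`1, x, y, x², xy, y², z, …`) — tests and the text format rely
on it.

Two facts the implementation leans on:

* **Beam-parallel unobservability.** `P` annihilates everything along the
  beam, so per image only two of the three 3D surfaces' combinations are
  identifiable. `fit_motion_3d()` solves the per-image linear system by
  minimum-norm least squares (SVD, relative rank threshold 1e−10), which
  places the unidentifiable combination at zero: the fitted 3D shift
  vectors are exactly perpendicular to the beam, and residuals equal the
  2D form's to machine precision. The 2D form is therefore the default —
  same fit, 12 instead of 18 parameters per image (bivariate).
* **Count identities.** Each surface has `(Dz+3)(D+2)(D+1)/6`
  coefficients in the bivariate (`Dz = 0`) and trivariate (`Dz = D`)
  families — 6 and 10 for quadratics, hence 18/30 (3D) and 12/20 (2D)
  parameters per image. For intermediate `Dz` the closed form undercounts
  the actual monomial set, so `count_coeffs()` uses the exact enumeration
  sum; the two agree on every family the package fits by default.

## The two-step fit and its gauges

Joint optimisation of positions, image parameters and motion surfaces is
badly conditioned, so fitting is split:

1. **Standard alignment.** With angles and magnification held at their
   input values the problem is *linear* in `(r_j, d_i)` and is solved
   directly by minimum-norm least squares; when rotation/tilt/
   magnification refinement is requested, a Levenberg–Marquardt iteration
   (analytic Jacobian, `ftol = 1e−10`, ≤200 iterations) starts from that
   linear solution. Gauge freedoms are removed explicitly: the marker
   centroid is pinned to the origin (a constant added to all `r_j` is
   indistinguishable from shifts), and under refinement the image nearest
   0° keeps its input rotation/tilt/magnification, killing the global
   rotation and scale degeneracies. Under-determined systems abort with
   the measurement deficit rather than returning garbage.
2. **Motion fit.** With `r_j`, `M_i`, `d_i` frozen, the image-plane model
   is linear in the surface coefficients: per image, a monomial design
   matrix at the fitted bead positions against the step-1 residuals.
   Because the zero polynomial is feasible, the motion-aware residual can
   never exceed the step-1 residual. The surfaces' constant terms are
   degenerate with `d_i`; they are gauge-masked to zero by default
   (`gauge_constant = TRUE`), and `d_i` is not refit (an experimental
   `refit_shifts` flag enables a joint per-image refit). Magnification is
   never refit in step 2 — the linear surface terms absorb it.

Numerical hygiene: bead coordinates are divided by their maximum absolute
value inside the solver (quadratic monomials of ±256 px coordinates are
hostile), and coefficients are rescaled back to pixel units; all rank
decisions use a relative 1e−10 SVD threshold.

**Scarce beads.** Each bead contributes two measurements per image, so a
full bivariate quadratic pair needs five beads per image after gauge
masking. Images below the threshold fall back automatically through
smoother families — pure z-terms, pure terms only, linear, none — and the
fallback is logged per image in the fit report. The
`measurements_to_unknowns_ratio()` diagnostic reports `2·n_obs / (2·terms)`
per image (constant terms counted, since they are part of the family's
bookkeeping even when gauge-fixed) and its series average; how such a
ratio is best bookkept is genuinely open, and this definition is the
package's.

## Leave-one-out cross-validation

Each bead in turn is excluded, the motion refit, and the bead's positions
predicted at its full-fit 3D coordinates; per-bead mean prediction errors
are averaged. By default only step 2 is refit per fold — the reference
frame stays that of the full standard alignment, so folds measure the
motion model and not frame wobble; `refit_step1 = TRUE` redoes both. The
headline number averages per-bead means (`pooling = "marker"`); pooling
over all observations is available, and the two differ only when beads
have unequal visibility. A LOO residual below the standard-alignment
residual validates the model over the bead-covered area; above it flags
overfit, which with few beads co-occurs with measurement/unknown ratios
near 1.

## Reconstruction

`reconstruct_wbp()` works on the *unaligned* stack: every voxel is
projected into every image through `M_i x + S_i(x) + d_i`, so alignment
and motion compensation cost no intermediate interpolation. Choices:

* The ramp filter (`|omega|`, DC removed, optional Hamming apodisation)
  is applied to the projections along the direction perpendicular to the
  tilt axis *before* backprojection — the conventional WBP order, chosen
  over weighting reconstructed slices afterwards because with per-voxel
  motion the mapping between a reconstructed slice and a detector line is
  no longer one-to-one. With motion enabled the `v` coordinate varies
  within a slice, so backprojection samples the full 2D image.
* Bilinear interpolation; a voxel whose tracked position leaves an image
  receives no contribution from it (no extrapolation), and voxels are
  normalised by their number of contributing images to avoid edge
  banding.
* With an all-zero motion model the compensated path reproduces the
  standard one to better than 1e−8 — compensation degrades nothing when
  no motion is modelled.

`track_position()` exposes the same mapping for arbitrary points, and
`extract_subtiltseries()` crops per-image patches at the tracked
(compensated) positions, recording the sub-pixel remainder per image, for
downstream per-particle processing.

## What the synthetic generator emulates — and what it does not

`make_scenario()` is the test substrate for every module: a two-branch
acquisition (default ±60° at 3°, branches from −21°, 41 images — the
well-conditioned thin-specimen layout), 40 beads uniform in a
512 × 512 × 150 px slab, per-image random shifts (2 px), Gaussian bead
localisation noise (0.5 px), and per-image quadratic image-plane surfaces
whose amplitude decays exponentially with accumulated dose,
`A_i = A_inf + (A0 − A_inf)·exp(−dose_i / tau)`, with
`tau = 12/ln 2` e⁻/Å² so the amplitude halves by ~12 e⁻/Å² — the exposure
at which residual curves of motion-blind alignments of real data flatten.

Two generator decisions deserve emphasis:

* **Per-image shape variation.** Each image's surfaces are
  `A_i (base + 0.5·jitter_i)` with `jitter_i` drawn at the rms scale of
  the base dome shape. A single master shape rescaled by `A_i` turns out
  to lie largely inside the span of the rigid model over 41 images (the
  per-bead and per-image free parameters absorb ~90% of it), which would
  make motion modelling look pointless — the opposite of what real
  tilt-series show. Real deformation differs image to image, which is the
  very reason the alignment models each image independently; the jitter
  encodes that.
* **Amplitude calibration.** No publication states dome amplitudes in
  pixels, but motion-blind alignments of real thin-specimen series
  consistently leave ~1.8–2 px mean residuals against ~0.7–0.8 px after
  motion modelling. The defaults (`A0 = 18` px decaying to
  `A_inf = 6.5` px) were calibrated once so the default scenario lands in
  that regime (measured over ten seeds: 1.88 px standard, 0.80 px
  motion-aware), then frozen.

The generator does **not** emulate physical image formation (CTF,
multiple scattering, detector MTF), frame-level movies within a tilt,
bead-tracking failures (tracks are perfect apart from Gaussian noise and
optional dropout), or temporal correlation of the deformation between
adjacent images. Passing tests therefore demonstrate the estimator's
correctness and conditioning under realistic geometry, noise and dose
behaviour — not robustness to tracking outliers or to model mismatch
beyond the jittered quadratic family.

A note on the noise-free recovery tests: with doming present, the step-1
least-squares solution absorbs part of the true motion into `r_j` and
`d_i` with a bead-dependent bias, so the composite two-step fit cannot
reach machine-precision residuals from `standard_align()` output — no
implementation could, it is a property of the split objective. The
recovery tests therefore adopt the generator's truth as the reference
alignment (the same route by which external IMOD-style parameters are
adopted in practice) and verify exact coefficient recovery there;
`standard_align()`'s own exact recovery is verified separately on
motion-free data.

## Problem sizes and determinism

The test suite and acceptance checks run at desk scale, chosen as the
smallest sizes that exercise every regime: 41-image series with 7–40
beads for alignment and LOO (Monte-Carlo over 10–20 seeds where a claim
is statistical), 256² × 41 phantom stacks and ≤64³ volumes for
reconstruction. All randomness flows from explicit integer seeds through
one generator; identical seeds give byte-identical scenarios, tracks and
rendered MRC stacks.

## Known limitations

* Beads are trusted as rigid-motion reporters of the specimen; biological
  material between beads is interpolated by the surfaces.
* No temporal smoothness constraints across images — each image is fit
  independently, which costs parameters on bead-poor series.
* Anisotropic magnification, skew and beam tilt are outside the
  projection model.
* SIRT/Fourier reconstruction, dose weighting and CTF handling are out of
  scope; the WBP here targets correctness, not 4k³ production throughput.
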