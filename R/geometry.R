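#' Per-image acquisition geometry of a tilt-series
#'
#' Builds the table of per-image acquisition parameters of a single-tilt-axis
#' tilt-series. One row per image, in stack (storage) order. The tilt axis is
#' the microscope Y-axis; the in-plane rotation `psi` acts about the
#' microscope Z-axis after projection; an optional pretilt `alpha` acts about
#' the microscope X-axis.
#'
#' Coordinate conventions used throughout the package:
#' * right-handed axes; positive tilt rotates +X towards -Z (the beam runs
#'   along -Z towards the detector);
#' * image coordinates `(u, v)` in pixels with the origin at the image
#'   centre, `u` rightward, `v` upward;
#' * sample coordinates in pixels with the origin at the centroid of the
#'   fitted fiducials.
#'
#' @param tilt_deg tilt angles in degrees, one per image, within \[-90, 90\].
#' @param psi_deg in-plane rotation(s) in degrees (recycled).
#' @param alpha_deg pretilt(s) about the X-axis in degrees (recycled).
#' @param mag isotropic magnification factor(s), strictly positive (recycled).
#' @param du,dv image shifts in pixels (recycled).
#' @param acq_index acquisition order (1 = first image exposed). Defaults to
#'   stack order. Must be a permutation of `1:N`.
#' @param branch acquisition branch id (1 or 2) per image.
#'
#' @return A tibble of class `tilt_geometry` with columns `image`,
#'   `tilt_deg`, `psi_deg`, `alpha_deg`, `mag`, `du`, `dv`, `acq_index`,
#'   `branch`.
#' @export
#' @examples
#' tilt_geometry(seq(-60, 60, by = 3))
tilt_geometry <- function(tilt_deg, psi_deg = 0, alpha_deg = 0, mag = 1,
                          du = 0, dv = 0, acq_index = seq_along(tilt_deg),
                          branch = 1L) {
  n <- length(tilt_deg)
  if (n < 1) stop("a tilt-series needs at least one image", call. = FALSE)
  if (any(!is.finite(tilt_deg)) || any(tilt_deg < -90 | tilt_deg > 90))
    stop("tilt angles must be finite and within [-90, 90] degrees",
         call. = FALSE)
  g <- tibble::tibble(
    image     = seq_len(n),
    tilt_deg  = as.numeric(tilt_deg),
    psi_deg   = rep_len(as.numeric(psi_deg), n),
    alpha_deg = rep_len(as.numeric(alpha_deg), n),
    mag       = rep_len(as.numeric(mag), n),
    du        = rep_len(as.numeric(du), n),
    dv        = rep_len(as.numeric(dv), n),
    acq_index = rep_len(as.integer(acq_index), n),
    branch    = rep_len(as.integer(branch), n)
  )
  if (any(g$mag <= 0)) stop("magnification must be > 0", call. = FALSE)
  if (anyDuplicated(g$acq_index) || !setequal(g$acq_index, seq_len(n)))
    stop("acq_index must be a permutation of 1:N", call. = FALSE)
  class(g) <- c("tilt_geometry", class(tibble::tibble()))
  attr(g, "tilt_axis_convention") <- "microscope Y-axis; +tilt maps +X to -Z"
  g
}

#' @export
print.tilt_geometry <- function(x, ...) {
  cat(sprintf("<tilt_geometry> %d images, tilt %g..%g deg\n",
              nrow(x), min(x$tilt_deg), max(x$tilt_deg)))
  NextMethod()
}

deg2rad <- function(x) x * pi / 180

#' Rotation matrix of one tilt image
#'
#' The 3x3 Euler rotation `Rz(psi) %*% Ry(theta) %*% Rx(alpha)` mapping
#' sample coordinates to microscope coordinates. `Ry` uses the convention in
#' which a positive tilt maps +X to -Z, so its first row is
#' `(cos theta, 0, sin theta)`.
#'
#' @param tilt_deg tilt angle theta (degrees), or a one-row `tilt_geometry`.
#' @param psi_deg in-plane rotation psi (degrees).
#' @param alpha_deg pretilt alpha (degrees).
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @export
rotation_matrix <- function(tilt_deg, psi_deg = 0, alpha_deg = 0) {
  if (is.data.frame(tilt_deg)) {
    stopifnot(nrow(tilt_deg) == 1L)
    g <- tilt_deg
    tilt_deg <- g$tilt_deg; psi_deg <- g$psi_deg; alpha_deg <- g$alpha_deg
  }
  th <- deg2rad(tilt_deg); ps <- deg2rad(psi_deg); al <- deg2rad(alpha_deg)
  ry <- matrix(c(cos(th), 0, sin(th),
                 0,       1, 0,
                 -sin(th), 0, cos(th)), 3, 3, byrow = TRUE)
  rx <- matrix(c(1, 0, 0,
                 0, cos(al), -sin(al),
                 0, sin(al),  cos(al)), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(ps), -sin(ps), 0,
                 sin(ps),  cos(ps), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  rz %*% ry %*% rx
}

#' Projection matrix of one tilt image
#'
#' The 2x3 matrix `M = mag * P * R` where `P` drops the microscope Z row
#' (projection along the beam) and `R` is [rotation_matrix()].
#'
#' @param g a one-row slice of a [tilt_geometry()], or a tilt angle in
#'   degrees.
#' @inheritParams rotation_matrix
#' @param mag isotropic magnification.
#' @return A 2x3 matrix.
#' @export
projection_matrix <- function(g, psi_deg = 0, alpha_deg = 0, mag = 1) {
  if (is.data.frame(g)) {
    stopifnot(nrow(g) == 1L)
    r <- rotation_matrix(g$tilt_deg, g$psi_deg, g$alpha_deg)
    mag <- g$mag
  } else {
    r <- rotation_matrix(g, psi_deg, alpha_deg)
  }
  mag * r[1:2, , drop = FALSE]
}

# list of 2x3 projection matrices, one per image
projection_matrices <- function(geom) {
  lapply(seq_len(nrow(geom)), function(i) projection_matrix(geom[i, ]))
}

#' Project a 3D sample point into one tilt image
#'
#' Applies the standard projection model `p = M r + d`: rotation by the image
#' Euler angles, projection along the beam, isotropic scaling, then the image
#' shift.
#'
#' @param g a one-row slice of a [tilt_geometry()].
#' @param r a length-3 numeric vector, or an `n x 3` matrix of sample-frame
#'   coordinates (pixels).
#' @return A length-2 vector `(u, v)` (or `n x 2` matrix) in pixels.
#' @export
#' @examples
#' g <- tilt_geometry(30)
#' project_marker(g[1, ], c(4, 2, 0))
project_marker <- function(g, r) {
  stopifnot(is.data.frame(g), nrow(g) == 1L)
  m <- projection_matrix(g)
  r <- rbind(r)
  p <- r %*% t(m)
  p[, 1] <- p[, 1] + g$du
  p[, 2] <- p[, 2] + g$dv
  if (nrow(p) == 1L) drop(p) else p
}

# beam direction expressed in the sample frame: third row of R
beam_direction <- function(g) {
  rotation_matrix(g)[3, ]
}
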