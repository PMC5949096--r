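#' Track a tomogram position through the tilt-series
#'
#' Projects an arbitrary sample-frame point into every tilt image with the
#' motion-aware projection model `p_i = M_i x + S_i(x) + d_i` (2D motion
#' form) or `p_i = M_i (x + D_i(x)) + d_i` (3D form); with no motion model
#' this is the standard projection.
#'
#' @param x length-3 numeric vector (sample-frame pixels).
#' @param sol a `tilt_alignment`.
#' @return A tibble with columns `image`, `u`, `v` (pixels, image-centre
#'   origin), one row per tilt image in stack order.
#' @export
track_position <- function(x, sol) {
  stopifnot(inherits(sol, "tilt_alignment"), length(x) == 3)
  uv <- project_points(matrix(x, 1, 3), sol)
  tibble::tibble(image = seq_len(nrow(sol$geometry)),
                 u = uv[, 1, ], v = uv[, 2, ])
}

# vectorised projection of an n x 3 point matrix into all images;
# returns an n x 2 x N array
project_points <- function(pts, sol) {
  n <- nrow(pts); nimg <- nrow(sol$geometry)
  out <- array(NA_real_, c(n, 2, nimg))
  for (i in seq_len(nimg)) {
    g <- sol$geometry[i, ]
    m <- projection_matrix(g)
    p0 <- pts
    if (!is.null(sol$motion) && sol$motion$form == "3d")
      p0 <- p0 + eval_motion(sol$motion, i, pts)
    p <- p0 %*% t(m)
    if (!is.null(sol$motion) && sol$motion$form == "2d")
      p <- p + eval_motion(sol$motion, i, pts)
    out[, 1, i] <- p[, 1] + g$du
    out[, 2, i] <- p[, 2] + g$dv
  }
  out
}

#' Ramp-filter projection lines
#'
#' Frequency-domain weighting by `|omega|` (normalised spatial frequency,
#' DC mapped to zero) along the first dimension — the direction
#' perpendicular to the tilt axis — with optional Hamming apodisation of
#' the high frequencies. This is the weighting step of weighted
#' backprojection, applied to the projections before backprojection. The
#' operator is linear and maps constant lines to zero.
#'
#' @param lines numeric vector, matrix or 3D array; filtering runs along
#'   the first dimension.
#' @param apodize `"none"` or `"hamming"`.
#' @return Filtered data with the shape of the input.
#' @export
ramp_filter <- function(lines, apodize = c("none", "hamming")) {
  apodize <- match.arg(apodize)
  dims <- dim(lines)
  x <- if (is.null(dims)) matrix(lines, ncol = 1) else
    matrix(lines, nrow = dims[1])
  n <- nrow(x)
  if (n < 2) stop("lines must have length >= 2", call. = FALSE)
  freq <- c(0:floor(n / 2), -((ceiling(n / 2) - 1):1))[1:n] / n
  w <- abs(freq)
  if (apodize == "hamming")
    w <- w * (0.54 + 0.46 * cos(2 * pi * freq))
  ft <- stats::mvfft(x) * w
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / n
  if (is.null(dims)) drop(out) else array(out, dims)
}

#' Motion-compensated weighted backprojection
#'
#' Reconstructs a tomogram from an (unaligned) tilt-series stack: every
#' voxel is projected into each image with the motion-aware model of
#' [track_position()] — the alignment and motion compensation are folded
#' into the projection mapping, so no intermediate interpolated stack is
#' produced — and the ramp-filtered images are sampled bilinearly at the
#' projected positions. Voxels are normalised by the number of images that
#' actually contribute (projections falling outside an image contribute
#' nothing).
#'
#' @param stack numeric array `nx x ny x N` (image u index first, v second),
#'   or an object returned by [read_mrc()].
#' @param sol a `tilt_alignment` whose geometry matches the stack.
#' @param shape output volume dimensions `c(nx, ny, nz)` in voxels; the
#'   volume is centred on the sample-frame origin.
#' @param use_motion apply the solution's motion model (ignored when the
#'   solution has none).
#' @param filter apply the ramp filter (plain backprojection when `FALSE`).
#' @param apodize passed to [ramp_filter()].
#' @param origin sample-frame coordinate of the volume centre.
#' @return A numeric array of class `tomo_volume` with attribute
#'   `voxel_size`.
#' @export
reconstruct_wbp <- function(stack, sol, shape, use_motion = TRUE,
                            filter = TRUE, apodize = c("none", "hamming"),
                            origin = c(0, 0, 0)) {
  apodize <- match.arg(apodize)
  stack <- as_stack_array(stack)
  nimg <- dim(stack)[3]
  if (nimg != nrow(sol$geometry))
    stop(sprintf("stack has %d images but geometry has %d", nimg,
                 nrow(sol$geometry)), call. = FALSE)
  stopifnot(length(shape) == 3, all(shape >= 1))
  if (filter) stack <- ramp_filter(stack, apodize)
  solp <- sol
  if (!use_motion) solp$motion <- NULL
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (dim(stack)[1] + 1) / 2; cy <- (dim(stack)[2] + 1) / 2
  xs <- seq_len(nx) - (nx + 1) / 2 + origin[1]
  ys <- seq_len(ny) - (ny + 1) / 2 + origin[2]
  zs <- seq_len(nz) - (nz + 1) / 2 + origin[3]
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  acc <- numeric(nrow(pts)); cnt <- numeric(nrow(pts))
  for (i in seq_len(nimg)) {
    uv <- project_points_one(pts, solp, i)
    iu <- uv[, 1] + cx; iv <- uv[, 2] + cy
    u0 <- floor(iu); v0 <- floor(iv)
    ok <- u0 >= 1 & u0 + 1 <= dim(stack)[1] & v0 >= 1 &
      v0 + 1 <= dim(stack)[2]
    if (!any(ok)) next
    fu <- iu[ok] - u0[ok]; fv <- iv[ok] - v0[ok]
    img <- stack[, , i]
    uo <- u0[ok]; vo <- v0[ok]
    val <- img[cbind(uo, vo)] * (1 - fu) * (1 - fv) +
      img[cbind(uo + 1, vo)] * fu * (1 - fv) +
      img[cbind(uo, vo + 1)] * (1 - fu) * fv +
      img[cbind(uo + 1, vo + 1)] * fu * fv
    acc[ok] <- acc[ok] + val
    cnt[ok] <- cnt[ok] + 1
  }
  vol <- acc / pmax(cnt, 1)
  vol <- array(vol, dim = c(nx, ny, nz))
  structure(vol, class = "tomo_volume",
            voxel_size = attr(stack, "voxel_size") %||% 1,
            origin = origin)
}

# projection of a point matrix into a single image (same model as
# project_points, avoiding the full N-image array)
project_points_one <- function(pts, sol, i) {
  g <- sol$geometry[i, ]
  m <- projection_matrix(g)
  p0 <- pts
  if (!is.null(sol$motion) && sol$motion$form == "3d")
    p0 <- p0 + eval_motion(sol$motion, i, pts)
  p <- p0 %*% t(m)
  if (!is.null(sol$motion) && sol$motion$form == "2d")
    p <- p + eval_motion(sol$motion, i, pts)
  cbind(p[, 1] + g$du, p[, 2] + g$dv)
}

as_stack_array <- function(stack) {
  if (is.list(stack) && !is.null(stack$data)) {
    out <- stack$data
    attr(out, "voxel_size") <- stack$voxel_size
    stack <- out
  }
  if (length(dim(stack)) == 2) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  stack
}

#' Extract the motion-compensated subtiltseries of a position
#'
#' Crops, from every tilt image, the patch centred on the tracked
#' projection of a sample-frame position — the per-particle tilt-series in
#' which the beam-induced sample motion is already compensated. Patches are
#' cropped at integer positions; the sub-pixel remainder of the tracked
#' coordinate is recorded per image. Images where the patch does not fit
#' inside the bounds are flagged absent.
#'
#' @param stack tilt-series array (`nx x ny x N`) or [read_mrc()] result.
#' @param sol a `tilt_alignment`.
#' @param centre length-3 sample-frame position (pixels).
#' @param patch_px patch side length in pixels.
#' @return An object of class `subtiltseries`: list with `patches`
#'   (`patch_px x patch_px x N`, `NA`-filled where absent), `table` (tibble
#'   `image, u, v, present, offset_u, offset_v`) and `centre`.
#' @export
extract_subtiltseries <- function(stack, sol, centre, patch_px = 32) {
  stack <- as_stack_array(stack)
  nimg <- dim(stack)[3]
  stopifnot(nimg == nrow(sol$geometry))
  trk <- track_position(centre, sol)
  half <- floor(patch_px / 2)
  cx <- (dim(stack)[1] + 1) / 2; cy <- (dim(stack)[2] + 1) / 2
  patches <- array(NA_real_, c(patch_px, patch_px, nimg))
  present <- logical(nimg)
  off_u <- off_v <- numeric(nimg)
  for (i in seq_len(nimg)) {
    iu <- round(trk$u[i] + cx); iv <- round(trk$v[i] + cy)
    us <- (iu - half):(iu - half + patch_px - 1)
    vs <- (iv - half):(iv - half + patch_px - 1)
    if (min(us) >= 1 && max(us) <= dim(stack)[1] &&
        min(vs) >= 1 && max(vs) <= dim(stack)[2]) {
      patches[, , i] <- stack[us, vs, i]
      present[i] <- TRUE
      off_u[i] <- trk$u[i] + cx - iu
      off_v[i] <- trk$v[i] + cy - iv
    }
  }
  structure(list(patches = patches,
                 table = tibble::tibble(image = trk$image, u = trk$u,
                                        v = trk$v, present = present,
                                        offset_u = off_u, offset_v = off_v),
                 centre = centre),
            class = "subtiltseries")
}

#' @export
print.subtiltseries <- function(x, ...) {
  cat(sprintf("<subtiltseries> %dx%d patches, %d/%d images present\n",
              dim(x$patches)[1], dim(x$patches)[2], sum(x$table$present),
              nrow(x$table)))
  invisible(x)
}
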