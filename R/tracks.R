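#' Fiducial marker track table
#'
#' Validates a table of measured fiducial positions: one row per observation
#' of a marker in a tilt image, coordinates in pixels with the origin at the
#' image centre. Markers observed in fewer than `min_obs` images are dropped
#' with a warning — too few views cannot constrain a 3D position.
#'
#' @param x a data frame with columns `marker`, `image`, `u`, `v` (extra
#'   columns are kept).
#' @param min_obs minimum number of images a marker must be observed in.
#' @return A tibble of class `marker_tracks`.
#' @export
marker_tracks <- function(x, min_obs = 3) {
  x <- tibble::as_tibble(x)
  need <- c("marker", "image", "u", "v")
  if (!all(need %in% names(x)))
    stop("tracks need columns marker, image, u, v", call. = FALSE)
  if (any(!is.finite(x$u)) || any(!is.finite(x$v)))
    stop("marker coordinates must be finite", call. = FALSE)
  if (anyDuplicated(x[c("marker", "image")]))
    stop("duplicate (marker, image) observations", call. = FALSE)
  x$image <- as.integer(x$image)
  counts <- table(x$marker)
  bad <- names(counts)[counts < min_obs]
  if (length(bad)) {
    warning(sprintf("dropping %d marker(s) observed in fewer than %d images",
                    length(bad), min_obs), call. = FALSE)
    x <- x[!(x$marker %in% bad), ]
  }
  if (nrow(x) == 0) stop("no usable marker observations", call. = FALSE)
  class(x) <- c("marker_tracks", class(tibble::tibble()))
  x
}

#' Read and write marker tracks
#'
#' The native format is a plain-text table with a header line
#' `marker image u v` (whitespace-separated, image indices 1-based,
#' coordinates in pixels from the image centre). `read_tracks` also accepts
#' IMOD `model2point -object` style output — four or five numeric columns
#' `object contour x y [z]` with 0-based slice indices and corner-origin
#' coordinates — via `format = "model2point"`, converting with the supplied
#' image size.
#'
#' @param path file path.
#' @param format `"native"` or `"model2point"`.
#' @param image_size `c(nx, ny)` in pixels; required for `"model2point"` to
#'   move the origin to the image centre (centre at `(size - 1) / 2` in
#'   0-based array coordinates).
#' @param min_obs passed to [marker_tracks()].
#' @return A `marker_tracks` tibble.
#' @export
read_tracks <- function(path, format = c("native", "model2point"),
                        image_size = NULL, min_obs = 3) {
  format <- match.arg(format)
  if (format == "native") {
    x <- utils::read.table(path, header = TRUE)
    return(marker_tracks(x, min_obs = min_obs))
  }
  if (is.null(image_size))
    stop("image_size = c(nx, ny) is required for model2point input",
         call. = FALSE)
  x <- utils::read.table(path, header = FALSE)
  if (ncol(x) == 4) x <- cbind(x[, 1, drop = FALSE], x)  # object only
  if (ncol(x) != 5)
    stop("model2point input needs 4 or 5 columns (object contour x y z)",
         call. = FALSE)
  names(x) <- c("object", "contour", "x", "y", "z")
  marker_tracks(tibble::tibble(
    marker = paste0(x$object, "_", x$contour),
    image  = as.integer(round(x$z)) + 1L,
    u      = x$x - (image_size[1] - 1) / 2,
    v      = x$y - (image_size[2] - 1) / 2
  ), min_obs = min_obs)
}

#' @rdname read_tracks
#' @param tracks a `marker_tracks` tibble.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)[c("marker", "image", "u", "v")]
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a .tlt tilt-angle file
#'
#' Plain text, one tilt angle in degrees per line, in stack order.
#'
#' @param path file path.
#' @param negate negate angles on import (the sign convention of a stack
#'   relative to the package's +tilt-maps-+X-to--Z convention is not fixed
#'   by the file format).
#' @return Numeric vector of tilt angles in degrees.
#' @export
read_tlt <- function(path, negate = FALSE) {
  a <- scan(path, quiet = TRUE)
  if (negate) -a else a
}

#' @rdname read_tlt
#' @param tilt_deg tilt angles in degrees.
#' @export
write_tlt <- function(tilt_deg, path) {
  writeLines(sprintf("%9.2f", tilt_deg), path)
  invisible(path)
}

#' Read and write IMOD-style .xf transform files
#'
#' Six whitespace-separated numbers per line: the 2x2 in-plane matrix
#' `a11 a12 a21 a22` (row-major) then shifts `dx dy`, one line per image.
#'
#' @param path file path.
#' @return A tibble with columns `a11, a12, a21, a22, dx, dy`.
#' @export
read_xf <- function(path) {
  x <- utils::read.table(path, header = FALSE)
  if (ncol(x) != 6)
    stop(sprintf(".xf file needs 6 columns, found %d", ncol(x)),
         call. = FALSE)
  names(x) <- c("a11", "a12", "a21", "a22", "dx", "dy")
  tibble::as_tibble(x)
}

#' @rdname read_xf
#' @param xf a data frame with columns `a11, a12, a21, a22, dx, dy`.
#' @export
write_xf <- function(xf, path) {
  writeLines(sprintf("%12.7f%12.7f%12.7f%12.7f%12.3f%12.3f",
                     xf$a11, xf$a12, xf$a21, xf$a22, xf$dx, xf$dy), path)
  invisible(path)
}
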