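# Minimal MRC2014 reader/writer: little-endian, modes 0 (int8), 1 (int16),
# 2 (float32) and 6 (uint16); data written as mode 2.

#' Read an MRC image stack or volume
#'
#' Parses the 1024-byte MRC header and returns the data as a numeric array
#' `nx x ny x nz` (first index fastest, as stored). Integer modes are
#' promoted to double exactly. Only little-endian files are supported.
#'
#' @param path file path.
#' @return A list with `data` (numeric array), `voxel_size` (Angstrom,
#'   from the cell dimensions) and `mode`.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr_int <- readBin(con, "integer", 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (any(c(nx, ny, nz) <= 0) || any(c(nx, ny, nz) > 1e5))
    stop("corrupt MRC header: bad dimensions", call. = FALSE)
  mxyz <- hdr_int[8:10]
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  seek(con, 1024)
  n <- as.double(nx) * ny * nz
  dat <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                             endian = "little")),
    stop(sprintf("unsupported MRC mode %d", mode), call. = FALSE))
  if (length(dat) != n)
    stop("MRC data shorter than header dimensions promise", call. = FALSE)
  vx <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else 1
  list(data = array(dat, c(nx, ny, nz)), voxel_size = vx, mode = mode)
}

#' Write an array as an MRC file (mode 2, float32)
#'
#' @param x numeric array (2D or 3D); a 2D array is written as a
#'   single-section file.
#' @param path file path.
#' @param voxel_size voxel/pixel size in Angstrom (stored in the cell
#'   dimensions).
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path, voxel_size = 1) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  stopifnot(length(dim(x)) == 3)
  nx <- dim(x)[1]; ny <- dim(x)[2]; nz <- dim(x)[3]
  con <- file(path, "wb"); on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4,
                             endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4,
                             endian = "little")
  wi(c(nx, ny, nz, 2L, 0L, 0L, 0L, nx, ny, nz))      # words 1-10
  wf(c(nx, ny, nz) * voxel_size)                     # cella
  wf(c(90, 90, 90))                                  # cellb
  wi(c(1L, 2L, 3L))                                  # mapc, mapr, maps
  wf(c(min(x), max(x), mean(x)))                     # dmin, dmax, dmean
  wi(c(0L, 0L))                                      # ispg, nsymbt
  wi(rep(0L, 25))                                    # extra
  wf(c(0, 0, 0))                                     # origin
  writeChar("MAP ", con, 4, eos = NULL)              # map id
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)   # machine stamp (LE)
  wf(stats::sd(x))                                   # rms
  wi(0L)                                             # nlabl
  writeBin(raw(800), con)                            # labels
  wf(as.numeric(x))
  invisible(path)
}
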