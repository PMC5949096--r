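#' Monomial term table of a polynomial deformation surface
#'
#' Enumerates the exponent triples `(m, n, l)` of the homogeneous polynomial
#' `P(x, y, z) = sum P_mnl x^m y^n z^l` with `m + n <= D - l` for each
#' z-power `l <= Dz`, in the package's pinned coefficient order: z-power `l`
#' outer (ascending), then total xy-degree (ascending), then `x`-power
#' descending within a degree. For the bivariate quadratic this gives
#' `1, x, y, x^2, xy, y^2`.
#'
#' @param degree polynomial degree `D` (non-negative integer).
#' @param z_degree z-degree `Dz`; 0 gives a bivariate (z-independent)
#'   surface.
#' @return A tibble with integer columns `m`, `n`, `l` and a `label` such as
#'   `"P210"`.
#' @export
poly_terms <- function(degree, z_degree = 0) {
  stopifnot(length(degree) == 1L, length(z_degree) == 1L)
  if (degree < 0 || z_degree < 0)
    stop("polynomial degrees must be non-negative", call. = FALSE)
  degree <- as.integer(degree); z_degree <- as.integer(z_degree)
  rows <- list()
  for (l in 0:z_degree) {
    for (t in 0:max(degree - l, 0L)) {
      if (degree - l < 0) break
      for (m in t:0) rows[[length(rows) + 1L]] <- c(m = m, n = t - m, l = l)
    }
  }
  tab <- tibble::as_tibble(do.call(rbind, rows))
  tab$label <- sprintf("P%d%d%d", tab$m, tab$n, tab$l)
  tab
}

#' Number of coefficients of one polynomial surface
#'
#' Counts the monomials `x^m y^n z^l` with `m + n <= D - l`, `l <= Dz`. In
#' the two families used for doming — bivariate (`Dz = 0`) and trivariate
#' (`Dz = D`) — this equals the closed form `(Dz + 3)(D + 2)(D + 1) / 6`:
#' a bivariate quadratic has 6 coefficients, a trivariate quadratic 10.
#'
#' @inheritParams poly_terms
#' @return An integer.
#' @export
#' @examples
#' count_coeffs(2, 0)  # 6
#' count_coeffs(2, 2)  # 10
count_coeffs <- function(degree, z_degree = 0) {
  if (degree < 0 || z_degree < 0)
    stop("polynomial degrees must be non-negative", call. = FALSE)
  l <- 0:min(z_degree, degree)
  as.integer(sum(choose(degree - l + 2, 2)))
}

#' Term masks implementing the parameter-reduction strategies
#'
#' When fiducials are scarce, the surfaces can be restricted to smoother
#' sub-families: `"pure_terms"` keeps only the pure powers `P_m00`, `P_0n0`,
#' `P_00l` (mixed terms removed); `"pure_z_only"` keeps the full xy-part
#' `P_mn0` but only pure powers `P_00l` in z; `"full"` keeps everything.
#'
#' @param mask_kind one of `"full"`, `"pure_terms"`, `"pure_z_only"`.
#' @inheritParams poly_terms
#' @return A logical vector, one entry per coefficient in pinned order.
#' @export
term_mask <- function(mask_kind = c("full", "pure_terms", "pure_z_only"),
                      degree, z_degree = 0) {
  mask_kind <- match.arg(mask_kind)
  tt <- poly_terms(degree, z_degree)
  switch(mask_kind,
    full        = rep(TRUE, nrow(tt)),
    pure_terms  = (tt$n == 0 & tt$l == 0) | (tt$m == 0 & tt$l == 0) |
                  (tt$m == 0 & tt$n == 0),
    pure_z_only = tt$l == 0 | (tt$m == 0 & tt$n == 0)
  )
}

#' Free parameters per tilt image of a motion model
#'
#' The per-image cost of modelling sample motion: three surfaces (`dx`,
#' `dy`, `dz`) in the 3D sample-frame form or two (`su`, `sv`) in the 2D
#' image-plane form, each with [count_coeffs()] coefficients, minus any
#' masked terms. Full quadratics give 18 (3D bivariate), 30 (3D trivariate),
#' 12 (2D bivariate) or 20 (2D trivariate) parameters.
#'
#' @param form `"3d"` (sample-frame triad) or `"2d"` (image-plane pair).
#' @inheritParams poly_terms
#' @param mask logical term mask (see [term_mask()]); default all enabled.
#' @return An integer.
#' @export
#' @examples
#' per_image_param_count("3d", 2, 0)  # 18
#' per_image_param_count("2d", 2, 2)  # 20
per_image_param_count <- function(form = c("2d", "3d"), degree, z_degree = 0,
                                  mask = NULL) {
  form <- match.arg(form)
  if (is.null(mask)) mask <- rep(TRUE, count_coeffs(degree, z_degree))
  stopifnot(length(mask) == count_coeffs(degree, z_degree))
  as.integer(sum(mask) * if (form == "3d") 3L else 2L)
}

#' Total motion parameters of a tilt-series (2D form)
#'
#' `N * (Dz + 3)(D + 2)(D + 1) / 3`: the full 2D image-plane motion model
#' over `N` images.
#'
#' @param n_images number of images `N`.
#' @inheritParams poly_terms
#' @return An integer.
#' @export
total_param_count <- function(n_images, degree, z_degree = 0) {
  stopifnot(n_images >= 0)
  as.integer(n_images) * per_image_param_count("2d", degree, z_degree)
}

#' Monomial design matrix
#'
#' Evaluates every monomial of the surface family at a set of points; column
#' order matches the pinned coefficient order of [poly_terms()], so
#' `basis %*% coefficients` evaluates the surface.
#'
#' @inheritParams poly_terms
#' @param points an `n x 3` matrix (or length-3 vector) of `(x, y, z)`
#'   coordinates.
#' @return An `n x count_coeffs(degree, z_degree)` matrix.
#' @export
monomial_basis <- function(degree, z_degree = 0, points) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3)
  tt <- poly_terms(degree, z_degree)
  b <- vapply(seq_len(nrow(tt)), function(k) {
    points[, 1]^tt$m[k] * points[, 2]^tt$n[k] * points[, 3]^tt$l[k]
  }, numeric(nrow(points)))
  matrix(b, nrow = nrow(points), dimnames = list(NULL, tt$label))
}

#' A polynomial deformation surface
#'
#' One scalar-valued polynomial surface `P(x, y, z)` in pixels, with its
#' coefficient vector in the pinned order and a term mask. Masked-out
#' coefficients are identically zero.
#'
#' @inheritParams poly_terms
#' @param coefficients numeric vector of length [count_coeffs()] (shorter
#'   vectors are zero-padded).
#' @param mask logical term mask; defaults to all enabled.
#' @return An object of class `poly_surface`.
#' @export
poly_surface <- function(degree, z_degree = 0, coefficients = NULL,
                         mask = NULL) {
  nc <- count_coeffs(degree, z_degree)
  if (is.null(coefficients)) coefficients <- numeric(nc)
  coefficients <- c(coefficients, numeric(max(0, nc - length(coefficients))))
  stopifnot(length(coefficients) == nc)
  if (is.null(mask)) mask <- rep(TRUE, nc)
  stopifnot(length(mask) == nc)
  coefficients[!mask] <- 0
  structure(list(degree = as.integer(degree),
                 z_degree = as.integer(z_degree),
                 coefficients = as.numeric(coefficients),
                 mask = as.logical(mask)),
            class = "poly_surface")
}

#' Evaluate a polynomial surface
#'
#' @param s a [poly_surface()].
#' @param points `n x 3` matrix or length-3 vector of coordinates (pixels).
#'   Bivariate surfaces (`z_degree = 0`) ignore the z column.
#' @return Numeric vector of surface values (pixels).
#' @export
eval_surface <- function(s, points) {
  stopifnot(inherits(s, "poly_surface"))
  drop(monomial_basis(s$degree, s$z_degree, points) %*% s$coefficients)
}

#' Per-image polynomial motion model
#'
#' Bundles one polynomial surface per motion component and per tilt image:
#' the 3D sample-frame form holds a triad `(dx, dy, dz)` of shifts per image,
#' the 2D image-plane form a pair `(su, sv)`. All surfaces of a model share
#' degree, z-degree and term mask. Coefficients are stored as one
#' `n_terms x n_components` matrix per image, in pixel units of raw sample
#' coordinates.
#'
#' @param form `"2d"` or `"3d"`.
#' @inheritParams poly_terms
#' @param coefficients list (one per image) of `n_terms x 2` (2D) or
#'   `n_terms x 3` (3D) coefficient matrices; missing entries are zero.
#' @param n_images number of images; required if `coefficients` is `NULL`.
#' @param mask logical term mask shared by all surfaces.
#' @param mask_kind label recording how the mask was produced.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(form = c("2d", "3d"), degree, z_degree = 0,
                         coefficients = NULL, n_images = NULL,
                         mask = NULL, mask_kind = "full") {
  form <- match.arg(form)
  nc <- count_coeffs(degree, z_degree)
  ncomp <- if (form == "3d") 3L else 2L
  comp_names <- if (form == "3d") c("dx", "dy", "dz") else c("su", "sv")
  if (is.null(mask)) mask <- rep(TRUE, nc)
  stopifnot(length(mask) == nc)
  if (is.null(coefficients)) {
    stopifnot(!is.null(n_images))
    coefficients <- replicate(n_images, matrix(0, nc, ncomp), simplify = FALSE)
  }
  coefficients <- lapply(coefficients, function(cc) {
    cc <- as.matrix(cc)
    stopifnot(nrow(cc) == nc, ncol(cc) == ncomp)
    cc[!mask, ] <- 0
    colnames(cc) <- comp_names
    cc
  })
  structure(list(form = form, degree = as.integer(degree),
                 z_degree = as.integer(z_degree),
                 mask = as.logical(mask), mask_kind = mask_kind,
                 coefficients = coefficients),
            class = "motion_model")
}

#' @export
print.motion_model <- function(x, ...) {
  cat(sprintf(
    "<motion_model> %s form, degree %d (z-degree %d), %d images, %d/%d terms enabled\n",
    x$form, x$degree, x$z_degree, length(x$coefficients), sum(x$mask),
    length(x$mask)))
  invisible(x)
}

n_images.motion_model <- function(m) length(m$coefficients)

#' Evaluate the motion of one image at sample points
#'
#' For the 2D form returns the image-plane shifts `(su, sv)`; for the 3D
#' form the sample-frame shifts `(dx, dy, dz)`.
#'
#' @param m a [motion_model()].
#' @param image image index (stack order).
#' @param points `n x 3` matrix or length-3 vector of sample coordinates.
#' @return An `n x 2` or `n x 3` matrix of shifts (pixels).
#' @export
eval_motion <- function(m, image, points) {
  stopifnot(inherits(m, "motion_model"))
  b <- monomial_basis(m$degree, m$z_degree, points)
  b %*% m$coefficients[[image]]
}

#' Project a 3D motion model to the 2D image-plane form
#'
#' The image-plane shifts are the projection of the sample-frame shifts:
#' `S_i(x, y, z) = M_i D_i(x, y, z)`, which holds coefficient-wise — each
#' 2D coefficient pair is the projection matrix applied to the matching 3D
#' coefficient triple.
#'
#' @param m3 a 3D-form [motion_model()].
#' @param geom the [tilt_geometry()] supplying the projection matrices.
#' @return A 2D-form `motion_model` with the same degree and mask.
#' @export
convert_3d_to_2d <- function(m3, geom) {
  stopifnot(inherits(m3, "motion_model"), m3$form == "3d")
  if (length(m3$coefficients) != nrow(geom))
    stop("motion model and geometry disagree on the number of images",
         call. = FALSE)
  pm <- projection_matrices(geom)
  co2 <- lapply(seq_len(nrow(geom)), function(i) {
    m3$coefficients[[i]] %*% t(pm[[i]])
  })
  motion_model("2d", m3$degree, m3$z_degree, coefficients = co2,
               mask = m3$mask, mask_kind = m3$mask_kind)
}

#' Write / read a motion model as plain text
#'
#' Serialises a [motion_model()] to a small versioned text format: a header
#' with image count, form, degrees and mask, then per image one line per
#' component surface with coefficients in the pinned order.
#'
#' @param m a `motion_model`.
#' @param path file path.
#' @return `write_motion_model` returns `path` invisibly;
#'   `read_motion_model` returns a `motion_model`.
#' @export
write_motion_model <- function(m, path) {
  stopifnot(inherits(m, "motion_model"))
  hdr <- c("# tiltmotion motion model v1",
           sprintf("n_images %d", length(m$coefficients)),
           sprintf("form %s", m$form),
           sprintf("degree %d", m$degree),
           sprintf("z_degree %d", m$z_degree),
           sprintf("mask_kind %s", m$mask_kind),
           paste(c("mask", as.integer(m$mask)), collapse = " "))
  body <- unlist(lapply(seq_along(m$coefficients), function(i) {
    cc <- m$coefficients[[i]]
    vapply(seq_len(ncol(cc)), function(k) {
      paste(c(sprintf("%d %s", i, colnames(cc)[k]),
              sprintf("%.17g", cc[, k])), collapse = " ")
    }, character(1))
  }))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_motion_model
#' @export
read_motion_model <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln)]
  kv <- function(key) sub(paste0("^", key, " "), "", ln[grepl(paste0("^", key, " "), ln)][1])
  n <- as.integer(kv("n_images"))
  form <- kv("form")
  degree <- as.integer(kv("degree"))
  z_degree <- as.integer(kv("z_degree"))
  mask_kind <- kv("mask_kind")
  mask <- as.logical(as.integer(strsplit(kv("mask"), "\\s+")[[1]]))
  nc <- count_coeffs(degree, z_degree)
  ncomp <- if (form == "3d") 3L else 2L
  body <- ln[grepl("^\\d+ (su|sv|dx|dy|dz) ", ln)]
  coef <- replicate(n, matrix(0, nc, ncomp), simplify = FALSE)
  comp_names <- if (form == "3d") c("dx", "dy", "dz") else c("su", "sv")
  for (b in body) {
    f <- strsplit(b, "\\s+")[[1]]
    i <- as.integer(f[1]); k <- match(f[2], comp_names)
    vals <- as.numeric(f[-(1:2)])
    if (length(vals) != nc)
      stop("malformed motion model line: wrong coefficient count",
           call. = FALSE)
    coef[[i]][, k] <- vals
  }
  motion_model(form, degree, z_degree, coefficients = coef, mask = mask,
               mask_kind = mask_kind)
}
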