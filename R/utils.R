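# Internal helpers shared across modules.
#
# Coordinate conventions (documented once, relied on everywhere):
#  * Raster space: pixels indexed (x, y), 0-based, x rightward, y DOWNWARD.
#    Matrices storing pixels have dim1 = x, dim2 = y (EBImage layout).
#  * Geometry space: angles in degrees, counterclockwise from the +x axis
#    with y increasing UPWARD.  Conversion raster -> geometry flips the sign
#    of y (and hence of angles).

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

wrap360 <- function(a) a %% 360
wrap180 <- function(a) a %% 180

#' @noRd
#' Signed angular difference a - b wrapped into (-180, 180].
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' @noRd
#' Axial (mod-180) absolute difference in degrees, in [0, 90].
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' @noRd
#' Evaluate `expr` under a temporary RNG seed, restoring the caller's
#' RNG state afterwards.  `seed = NULL` leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' @noRd
#' Deterministic child seed for sub-stream `i` of a parent seed.
child_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 1103 * i) %% 2147483647
}

#' @noRd
#' Vectorised ray-casting point-in-polygon test.  `px`, `py` are point
#' coordinates; `poly` an n x 2 matrix of vertices (closed implicitly).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- ((ys[k] > py) != (ye[k] > py))
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) / (ye[k] - ys[k]) * (xe[k] - xs[k])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

#' @noRd
#' Extract the pixel matrix (dim1 = x, dim2 = y) from anything image-like.
pixel_matrix <- function(image) {
  if (inherits(image, "image_field")) return(image$pixels)
  if (inherits(image, "Image")) return(EBImage::imageData(image))
  if (is.matrix(image)) return(image)
  stop("expected an image_field, EBImage Image, or numeric matrix")
}
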