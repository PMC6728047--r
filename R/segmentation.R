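# Halo/core segmentation.
#
# Automates the manual tracing step: the outline of each explant halo and of
# its core are extracted as closed polygons.  The halo is recovered by global
# thresholding followed by morphological closing (to bridge the gaps between
# individual neurites) and hole filling; the core is the bright (dense)
# interior component of each halo.  Explants near the dish edge, touching the
# image border, or sharing a halo with a neighbor are flagged and excluded
# from quantification, mirroring the inclusion rule that only explants away
# from the dish edge and physically separated from each other are measured.

#' Construct an explant contour
#'
#' A closed polygon in 0-based raster pixel coordinates (x rightward,
#' y downward) delimiting a halo or core region.
#'
#' @param vertices n x 2 matrix of (x, y) vertices, ordered along the
#'   boundary; the polygon is closed implicitly.
#' @param role `"halo"` or `"core"`.
#' @param explant_id integer id linking halo and core of the same explant.
#' @return object of class `explant_contour`.
#' @export
explant_contour <- function(vertices, role = c("halo", "core"),
                            explant_id = 1L) {
  role <- match.arg(role)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L) stop("a contour needs at least 3 vertices")
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  structure(list(vertices = vertices, role = role,
                 explant_id = as.integer(explant_id)),
            class = "explant_contour")
}

#' @export
print.explant_contour <- function(x, ...) {
  cat(sprintf("%s contour, explant %d: %d vertices, area %.1f px^2\n",
              x$role, x$explant_id, nrow(x$vertices), contour_area(x)))
  invisible(x)
}

#' Area enclosed by a contour
#'
#' Shoelace (Gauss) polygon area of a closed contour, in squared pixels.
#'
#' @param contour an [explant_contour()] or an n x 2 vertex matrix (n >= 3).
#' @return positive area in px^2.
#' @examples
#' sq <- explant_contour(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), "core")
#' contour_area(sq)  # 1
#' @export
contour_area <- function(contour) {
  v <- if (inherits(contour, "explant_contour")) contour$vertices
       else as.matrix(contour)
  if (nrow(v) < 3L) stop("degenerate contour: fewer than 3 vertices")
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  abs(sum(x * y2 - x2 * y)) / 2
}

#' @noRd
#' Normalize a pixel matrix to [0, 1] as a bright-on-dark image, inverting
#' dark-on-light input.  `polarity = NULL` auto-detects from the intensity
#' distribution: the background is the majority phase, so a median above the
#' mid-range implies a bright background (dark-on-light stain).
normalize_polarity <- function(px, polarity = NULL) {
  rng <- range(px)
  if (diff(rng) == 0) stop("image is constant: nothing to segment")
  px <- (px - rng[1]) / diff(rng)
  if (is.null(polarity))
    polarity <- if (stats::median(px) > 0.5) "dark_on_light" else "bright_on_dark"
  if (polarity == "dark_on_light") px <- 1 - px
  px
}

#' Segment explant halos and cores
#'
#' Extracts one (halo, core) contour pair per explant from a dish or
#' single-explant image.  The image is normalized to bright-on-dark,
#' thresholded (Otsu by default), morphologically closed so the radial
#' neurites merge into a solid halo, and hole-filled; connected components of
#' at least `min_area` px^2 are halo candidates.  Within each halo, the core
#' is the largest connected component above a second threshold computed on
#' the halo's interior intensities.  Contours are traced along boundary pixel
#' centers (pixel resolution).
#'
#' Quality flags per explant: `touches_image_edge` (halo meets the image
#' border), `touches_dish_edge` (halo comes within `edge_margin` of the dish
#' boundary, when a dish geometry is supplied), `merged_with_neighbor`
#' (several cores share one halo component), `no_core` (no core found).
#' Flagged explants are carried in the result but marked `excluded`.
#'
#' @param image an [image_field()], `EBImage` Image, or pixel matrix.
#' @param polarity stain polarity; NULL auto-detects.
#' @param threshold halo threshold on the normalized \[0, 1\] scale; NULL uses
#'   Otsu's method.
#' @param min_area minimal halo component area, px^2.
#' @param close_size diameter (px) of the disc brush used to close gaps
#'   between neurites.
#' @param dish_center,dish_radius optional dish geometry (0-based pixel
#'   coords / px) enabling the dish-edge flag.
#' @param edge_margin distance from the dish boundary within which explants
#'   are flagged, px.
#' @return object of class `segmentation_result`: list with `pairs` (list of
#'   `list(halo, core, explant_id, flags)`) and `flags` (one data frame row
#'   per explant).  An empty result (with a warning) when no foreground is
#'   found.
#' @export
segment_explants <- function(image, polarity = NULL, threshold = NULL,
                             min_area = 400, close_size = 19,
                             dish_center = NULL, dish_radius = NULL,
                             edge_margin = 40) {
  px <- pixel_matrix(image)
  if (inherits(image, "image_field") && is.null(polarity))
    polarity <- image$polarity
  if (nrow(px) < 64 || ncol(px) < 64) stop("image must be at least 64 x 64")
  px <- normalize_polarity(px, polarity)
  thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(px)) else threshold
  fg <- EBImage::Image(px > thr)
  empty <- structure(list(pairs = list(),
                          flags = empty_flags_table()),
                     class = "segmentation_result")
  if (sum(fg) < min_area) {
    warning("no foreground found")
    return(empty)
  }
  if (mean(fg) > 0.45) {
    # a global threshold splitting the image roughly in half means there is
    # no figure/ground structure (e.g. a featureless or pure-noise field)
    warning("no foreground structure: threshold splits the image in half")
    return(empty)
  }
  brush <- EBImage::makeBrush(max(3, 2 * (close_size %/% 2) + 1), "disc")
  halo_mask <- EBImage::fillHull(EBImage::closing(fg, brush))
  labels <- EBImage::bwlabel(halo_mask)
  lab <- EBImage::imageData(labels)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) {
    warning("no halo component of at least min_area px^2")
    return(empty)
  }

  pairs <- list(); rows <- list(); id <- 0L
  nx <- nrow(px); ny <- ncol(px)
  for (comp in keep) {
    hmask <- lab == comp
    inside <- px[hmask]
    # core threshold: Otsu on the halo FOREGROUND intensities separates the
    # dense bright core from the neurite field (the interior also contains
    # background pixels in the gaps between neurites, which would dominate)
    fgvals <- inside[inside > thr]
    cthr <- if (length(fgvals) > 50)
      tryCatch(EBImage::otsu(EBImage::Image(matrix(fgvals))),
               error = function(e) stats::quantile(fgvals, 0.9))
    else stats::quantile(inside, 0.95)
    cmask_all <- hmask & (px > cthr)
    clab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(cmask_all)))
    csizes <- tabulate(clab[clab > 0])
    min_core <- max(25, 0.001 * sizes[comp])
    cores <- which(csizes >= min_core)
    merged <- length(cores) > 1L
    halo_cont <- trace_contour(hmask)
    edge_img <- any(hmask[c(1, nx), ]) || any(hmask[, c(1, ny)])
    edge_dish <- FALSE
    if (!is.null(dish_center) && !is.null(dish_radius)) {
      d <- sqrt((halo_cont[, 1] - dish_center[1])^2 +
                (halo_cont[, 2] - dish_center[2])^2)
      edge_dish <- any(d > dish_radius - edge_margin)
    }
    if (!length(cores)) {
      id <- id + 1L
      rows[[id]] <- flags_row(id, TRUE, edge_img, edge_dish, FALSE)
      pairs[[id]] <- list(halo = explant_contour(halo_cont, "halo", id),
                          core = NULL, explant_id = id,
                          flags = rows[[id]])
      next
    }
    for (cc in cores) {
      id <- id + 1L
      core_cont <- trace_contour(clab == cc)
      rows[[id]] <- flags_row(id, FALSE, edge_img, edge_dish, merged)
      pairs[[id]] <- list(halo = explant_contour(halo_cont, "halo", id),
                          core = explant_contour(core_cont, "core", id),
                          explant_id = id, flags = rows[[id]])
    }
  }
  structure(list(pairs = pairs, flags = do.call(rbind, rows)),
            class = "segmentation_result")
}

#' @noRd
empty_flags_table <- function() {
  data.frame(explant_id = integer(), no_core = logical(),
             touches_image_edge = logical(), touches_dish_edge = logical(),
             merged_with_neighbor = logical(), excluded = logical())
}

#' @noRd
flags_row <- function(id, no_core, edge_img, edge_dish, merged) {
  data.frame(explant_id = id, no_core = no_core,
             touches_image_edge = edge_img, touches_dish_edge = edge_dish,
             merged_with_neighbor = merged,
             excluded = no_core || edge_img || edge_dish || merged)
}

#' @noRd
#' Boundary polygon (0-based pixel-center coordinates) of a logical mask,
#' via EBImage's contour tracer on the largest component.
trace_contour <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask + 0))
  if (!length(oc)) stop("empty mask: no contour")
  oc[[which.max(vapply(oc, nrow, 1L))]]
}

#' @export
print.segmentation_result <- function(x, ...) {
  n <- length(x$pairs)
  cat(sprintf("segmentation_result: %d explant(s), %d excluded\n",
              n, sum(x$flags$excluded)))
  if (n) print(x$flags)
  invisible(x)
}
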