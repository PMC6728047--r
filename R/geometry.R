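# Ellipse fitting and the percent asymmetry index.
#
# The index quantifies how far the explant core sits from the center of its
# halo: ellipses are fit to both contours by the method of moments (same
# centroid, area and second central moments as the filled polygon, the
# ImageJ "Fit Ellipse" convention), the core-center offset is projected onto
# the halo's major axis, and the asymmetry is that projection as a percent of
# the semi-major length.  0% = core at the halo center; 100% = core at an end
# of the major axis (a halo extending from one side only, never observed in
# real cultures).  The direction of the LONGEST neurites is opposite the
# core displacement: the core sits closer to the short-neurite side.

#' Fit an ellipse to a contour by the method of moments
#'
#' Returns the ellipse with the same centroid, area, and second central
#' moments as the region enclosed by the contour.  Moments of the filled
#' polygon are computed exactly by Green's theorem; the axes come from the
#' eigendecomposition of the region covariance matrix, rescaled so the
#' ellipse area equals the polygon area.
#'
#' @param contour an [explant_contour()] or n x 2 vertex matrix in raster
#'   coordinates (x rightward, y downward).
#' @return object of class `ellipse_fit`: list with `center` (x, y in raster
#'   coordinates), `semi_major`, `semi_minor` (px) and `major_axis_angle_deg`
#'   in \[0, 180), measured counterclockwise from +x with y UP (geometry
#'   convention).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 721)[-721]
#' circ <- cbind(50 * cos(th), 50 * sin(th))
#' fit_ellipse(circ)
#' @export
fit_ellipse <- function(contour) {
  v <- if (inherits(contour, "explant_contour")) contour$vertices
       else as.matrix(contour)
  if (nrow(v) < 3L) stop("degenerate contour: fewer than 3 vertices")
  n <- nrow(v)
  x <- v[, 1]; y <- v[, 2]
  x2 <- x[c(2:n, 1)]; y2 <- y[c(2:n, 1)]
  cross <- x * y2 - x2 * y
  A <- sum(cross) / 2                      # signed area
  if (abs(A) < 1e-9) stop("degenerate contour: zero area (collinear vertices)")
  cx <- sum((x + x2) * cross) / (6 * A)
  cy <- sum((y + y2) * cross) / (6 * A)
  # second moments of area about the origin (Green's theorem)
  sxx <- sum((x^2 + x * x2 + x2^2) * cross) / 12
  syy <- sum((y^2 + y * y2 + y2^2) * cross) / 12
  sxy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cross) / 24
  # central covariance of the filled region
  cxx <- sxx / A - cx^2
  cyy <- syy / A - cy^2
  cxy <- sxy / A - cx * cy
  eg <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (lam[1] <= 0) stop("degenerate contour: collinear vertices")
  a <- 2 * sqrt(lam[1]); b <- 2 * sqrt(lam[2])
  if (b <= 0) stop("degenerate contour: zero minor axis")
  # rescale so the ellipse area equals the region area (ImageJ convention)
  s <- sqrt(abs(A) / (pi * a * b))
  a <- a * s; b <- b * s
  vec <- eg$vectors[, 1]
  # raster y runs downward; geometry angles are CCW with y up
  ang <- wrap180(rad2deg(atan2(-vec[2], vec[1])))
  structure(list(center = c(x = cx, y = cy), semi_major = a, semi_minor = b,
                 major_axis_angle_deg = ang),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "ellipse_fit: center (%.2f, %.2f), semi-axes %.2f x %.2f px, major axis %.2f deg\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor,
    x$major_axis_angle_deg))
  invisible(x)
}

#' Percent neurite-length asymmetry of an explant
#'
#' Computes the asymmetry index from the halo and core ellipse fits: the
#' core-center offset from the halo center is projected onto the halo's
#' major axis and expressed as a percent of the semi-major length (the
#' distance from the halo center to the nearer end of the major axis).
#' Offsets along the minor axis contribute nothing.  The long-neurite
#' orientation points along the major axis AWAY from the core displacement
#' (the core sits nearer the short-neurite side).
#'
#' @param halo,core [fit_ellipse()] results for the halo and core contours.
#' @param halo_area,core_area optional region areas (px^2) to attach; default
#'   to the fitted ellipse areas.
#' @param circular_tol halos with axis ratio below `1 + circular_tol` are
#'   near-circular: the major-axis direction is numerically unstable, so the
#'   measurement is flagged `low_confidence` (but still returned).
#' @return object of class `asymmetry_measurement`: `asymmetry_pct` in
#'   \[0, 100\], `long_orientation_deg` in \[0, 360), the two ellipse fits,
#'   areas, and flags.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 721)[-721]
#' halo <- fit_ellipse(cbind(200 * cos(th), -120 * sin(th)))
#' core <- fit_ellipse(cbind(100 + 30 * cos(th), -30 * sin(th)))
#' asymmetry_index(halo, core)  # 50% asymmetry, long neurites toward 180 deg
#' @export
asymmetry_index <- function(halo, core, halo_area = NULL, core_area = NULL,
                            circular_tol = 0.02) {
  stopifnot(inherits(halo, "ellipse_fit"), inherits(core, "ellipse_fit"))
  th <- deg2rad(halo$major_axis_angle_deg)
  u <- c(cos(th), sin(th))
  # geometry coordinates: flip y of the raster offset
  v <- c(core$center[1] - halo$center[1],
         -(core$center[2] - halo$center[2]))
  s <- sum(v * u)
  d <- abs(s)
  if (d > halo$semi_major * (1 + 1e-9))
    stop("core center lies beyond the end of the halo major axis")
  d <- min(d, halo$semi_major)
  pct <- 100 * d / halo$semi_major
  long_dir <- if (s > 0) wrap360(halo$major_axis_angle_deg + 180)
              else halo$major_axis_angle_deg
  structure(list(
    asymmetry_pct = pct,
    long_orientation_deg = wrap360(long_dir),
    halo_ellipse = halo, core_ellipse = core,
    halo_area = if (is.null(halo_area))
      pi * halo$semi_major * halo$semi_minor else halo_area,
    core_area = if (is.null(core_area))
      pi * core$semi_major * core$semi_minor else core_area,
    low_confidence = halo$semi_major / halo$semi_minor < 1 + circular_tol,
    excluded = FALSE, reason = NA_character_
  ), class = "asymmetry_measurement")
}

#' @export
print.asymmetry_measurement <- function(x, ...) {
  cat(sprintf("asymmetry %.1f%%, long neurites toward %.1f deg%s\n",
              x$asymmetry_pct, x$long_orientation_deg,
              if (x$low_confidence) " (near-circular halo, low confidence)" else ""))
  invisible(x)
}

#' Measure every explant of a segmented dish
#'
#' Applies the ellipse fits and the asymmetry index to each (halo, core)
#' pair of a [segment_explants()] result.  Explants flagged by segmentation
#' (edge, merged, missing core) are carried through as excluded rows with
#' their reason; per-explant fitting failures also become exclusions rather
#' than errors.
#'
#' @param seg a `segmentation_result`.
#' @return data frame of class `dish_measurements`, one row per explant:
#'   `explant_id`, `asymmetry_pct`, `long_orientation_deg`, `halo_area`,
#'   `core_area` (shoelace contour areas), `low_confidence`, `excluded`,
#'   `reason`.  The measurement objects are attached as the
#'   `"measurements"` attribute.
#' @export
measure_dish <- function(seg) {
  stopifnot(inherits(seg, "segmentation_result"))
  rows <- list(); ms <- list()
  for (p in seg$pairs) {
    fl <- p$flags
    reason <- if (fl$no_core) "no_core"
      else if (fl$merged_with_neighbor) "merged_with_neighbor"
      else if (fl$touches_dish_edge) "touches_dish_edge"
      else if (fl$touches_image_edge) "touches_image_edge"
      else NA_character_
    if (!is.na(reason)) {
      rows[[length(rows) + 1L]] <- data.frame(
        explant_id = p$explant_id, asymmetry_pct = NA_real_,
        long_orientation_deg = NA_real_,
        halo_area = contour_area(p$halo),
        core_area = if (is.null(p$core)) NA_real_ else contour_area(p$core),
        low_confidence = NA, excluded = TRUE, reason = reason)
      next
    }
    m <- tryCatch({
      hf <- fit_ellipse(p$halo); cf <- fit_ellipse(p$core)
      asymmetry_index(hf, cf,
                      halo_area = contour_area(p$halo),
                      core_area = contour_area(p$core))
    }, error = function(e) e)
    if (inherits(m, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        explant_id = p$explant_id, asymmetry_pct = NA_real_,
        long_orientation_deg = NA_real_,
        halo_area = contour_area(p$halo), core_area = NA_real_,
        low_confidence = NA, excluded = TRUE,
        reason = conditionMessage(m))
      next
    }
    ms[[as.character(p$explant_id)]] <- m
    rows[[length(rows) + 1L]] <- data.frame(
      explant_id = p$explant_id, asymmetry_pct = m$asymmetry_pct,
      long_orientation_deg = m$long_orientation_deg,
      halo_area = m$halo_area, core_area = m$core_area,
      low_confidence = m$low_confidence, excluded = FALSE,
      reason = NA_character_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(explant_id = integer(), asymmetry_pct = numeric(),
               long_orientation_deg = numeric(), halo_area = numeric(),
               core_area = numeric(), low_confidence = logical(),
               excluded = logical(), reason = character())
  attr(out, "measurements") <- ms
  class(out) <- c("dish_measurements", "data.frame")
  out
}
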