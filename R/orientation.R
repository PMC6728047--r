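# Blinded morphological-orientation protocol.
#
# Real halos can be morphologically asymmetric (dense short side with
# club-like endings vs a sparse side with longer, thinner neurites) even when
# length asymmetry is subtle.  The protocol scores that cue without knowing
# the true orientation: each explant is cropped in a round field (no square-
# frame cues), rotated by its own random angle, scored by drawing an
# "equatorial" line separating the two morphologically distinct halves, and
# the result is decoded by reversing the rotation.  The axis of orientation
# is the perpendicular to the equator pointing toward the sparser half.
# Here the human scorer is replaced by an automated morphology surrogate
# (and, for testing the machinery, by simulated noisy observers).
#
# Orientations are directions mod 360 (not axes mod 180): the protocol
# resolves the sense of the axis by asking which side is the sparser one.

#' Circularly crop and randomly rotate an explant image
#'
#' Crops a round field around the explant (everything outside the disk is
#' set to the background level, eliminating square-edge cues) and rotates it
#' counterclockwise by a random angle, returned alongside the image so the
#' measurement can later be decoded.  Rotation uses bilinear interpolation
#' and the disk mask is re-applied afterwards so no frame cues leak in.
#'
#' @param image an [image_field()] or pixel matrix.
#' @param center (x, y) crop center in 0-based raster coordinates; default is
#'   the image center.
#' @param radius crop radius, px; must fit inside the image.
#' @param rng_seed optional seed for the rotation draw.
#' @param angle_deg fixed rotation (degrees CCW) overriding the random draw;
#'   used by tests and decoding checks.
#' @return list with `image` (the cropped, rotated [image_field()]) and
#'   `applied_rotation_deg` in \[0, 360).
#' @export
blind_rotate <- function(image, center = NULL, radius = NULL, rng_seed = NULL,
                         angle_deg = NULL) {
  px <- pixel_matrix(image)
  nx <- nrow(px); ny <- ncol(px)
  if (is.null(center)) center <- c((nx - 1) / 2, (ny - 1) / 2)
  if (is.null(radius)) radius <- floor(min(nx, ny) / 2) - 1
  if (center[1] - radius < 0 || center[1] + radius > nx - 1 ||
      center[2] - radius < 0 || center[2] + radius > ny - 1)
    stop("crop radius exceeds image bounds")
  rot <- if (!is.null(angle_deg)) wrap360(angle_deg)
         else with_seed(rng_seed, stats::runif(1, 0, 360))
  r <- floor(radius)
  xs <- (round(center[1]) - r):(round(center[1]) + r) + 1L
  ys <- (round(center[2]) - r):(round(center[2]) + r) + 1L
  crop <- px[xs, ys]
  bg <- stats::quantile(crop, 0.1)
  side <- 2L * r + 1L
  cc <- r  # 0-based center of the crop
  disk <- (row(crop) - 1 - cc)^2 + (col(crop) - 1 - cc)^2 <= radius^2
  crop[!disk] <- bg
  # EBImage::rotate is clockwise in raster display; CCW = negative angle
  rimg <- EBImage::rotate(EBImage::Image(crop), angle = -rot,
                          output.dim = c(side, side), bg.col = bg)
  out <- EBImage::imageData(rimg)
  out[!disk] <- bg
  pol <- if (inherits(image, "image_field")) image$polarity else "bright_on_dark"
  list(image = image_field(out, polarity = pol), applied_rotation_deg = rot)
}

#' Decode a blinded orientation measurement
#'
#' Reverses the random rotation: an orientation measured on an image rotated
#' CCW by `applied_rotation_deg` corresponds to `measured - applied` in the
#' original frame.
#'
#' @param measured_deg orientation measured on the rotated image, degrees.
#' @param applied_rotation_deg the rotation returned by [blind_rotate()].
#' @return decoded orientation in \[0, 360).
#' @export
decode_orientation <- function(measured_deg, applied_rotation_deg) {
  wrap360(measured_deg - applied_rotation_deg)
}

#' Automated morphology-based orientation of a halo
#'
#' Surrogate for the human observer: finds the direction that best separates
#' the two morphologically distinct halves of the halo.  Around the core
#' center, the halo annulus is profiled in 1-degree angular bins (radial
#' extent of the outgrowth and areal density of stained pixels).  For every
#' candidate direction on a 1-degree grid the annulus is split into two
#' half-disks by the perpendicular equator, and the direction maximizing the
#' combined contrast -- greater radial extent AND lower density ahead -- is
#' returned.  That is the direction of the sparser half with the longer,
#' thinner neurites, i.e. the long-neurite orientation.
#'
#' @param image an [image_field()] or pixel matrix (may be a rotated blinded
#'   crop).
#' @param halo,core [explant_contour()]s of the halo and core in the SAME
#'   image frame.
#' @param min_contrast floor on the relative modulation (combined half-disk
#'   contrast divided by its mean level) below which the halo is considered
#'   radially symmetric and `NA` is returned (no-orientation sentinel).
#' @param polarity stain polarity; NULL auto-detects.
#' @return orientation in \[0, 360) degrees (geometry convention) pointing
#'   toward the sparser/longer side, or `NA` when no reliable contrast
#'   exists.  The combined contrast is attached as attribute `"contrast"`.
#' @export
morphology_orientation <- function(image, halo, core, min_contrast = 0.08,
                                   polarity = NULL) {
  px <- pixel_matrix(image)
  if (inherits(image, "image_field") && is.null(polarity))
    polarity <- image$polarity
  px <- normalize_polarity(px, polarity)
  thr <- EBImage::otsu(EBImage::Image(px))
  core_fit <- fit_ellipse(core)
  cx <- core_fit$center[1]; cy <- core_fit$center[2]
  r_core <- sqrt(contour_area(core) / pi)

  fg <- which(px > thr, arr.ind = TRUE)
  fx <- fg[, 1] - 1 - cx
  fy <- fg[, 2] - 1 - cy
  rr <- sqrt(fx^2 + fy^2)
  keep <- rr > r_core * 1.1 &
    point_in_polygon(fg[, 1] - 1, fg[, 2] - 1,
                     if (inherits(halo, "explant_contour")) halo$vertices
                     else halo)
  if (sum(keep) < 50) return(structure(NA_real_, contrast = 0))
  # geometry angles: y flips sign
  ang <- wrap360(rad2deg(atan2(-fy[keep], fx[keep])))
  rr <- rr[keep]
  bin <- floor(ang) %% 360 + 1L

  counts <- rep(0, 360)
  tab <- table(bin)
  counts[as.integer(names(tab))] <- as.numeric(tab)
  # radial extent per bin from the halo CONTOUR (continuous around the rim;
  # foreground pixels would leave holes in thinned sectors and bias the
  # half-disk means), empty bins interpolated circularly
  hv <- if (inherits(halo, "explant_contour")) halo$vertices else halo
  hx <- hv[, 1] - cx; hy <- hv[, 2] - cy
  h_ang <- wrap360(rad2deg(atan2(-hy, hx)))
  h_rad <- sqrt(hx^2 + hy^2)
  h_bin <- floor(h_ang) %% 360 + 1L
  extent <- rep(NA_real_, 360)
  hagg <- tapply(h_rad, h_bin, max)
  extent[as.integer(names(hagg))] <- hagg
  if (anyNA(extent)) {
    filled <- which(!is.na(extent))
    extent <- stats::approx(x = c(filled, filled + 360),
                            y = extent[c(filled, filled)],
                            xout = 1:360 + 360, rule = 2)$y
  }
  # areal density within each bin's own reach: counts over the wedge area
  # up to that bin's extent (a global outer radius would credit the
  # longer-reaching side with extra area and flip the sparseness cue)
  wedge <- 0.5 * (pmax(extent, r_core + 1)^2 - r_core^2) * (pi / 180)
  density <- counts / wedge

  th_bin <- deg2rad((0:359) + 0.5)
  psi <- deg2rad(0:359)
  # half-disk membership matrix: rows = candidate direction, cols = bins
  half <- outer(psi, th_bin, function(p, t) cos(t - p) > 0)
  m_ext_long <- (half %*% extent) / rowSums(half)
  m_ext_short <- ((!half) %*% extent) / rowSums(!half)
  m_den_long <- (half %*% density) / rowSums(half)
  m_den_short <- ((!half) %*% density) / rowSums(!half)
  ext_diff <- as.numeric(m_ext_long - m_ext_short)
  den_diff <- as.numeric(m_den_short - m_den_long)
  rel <- ext_diff / mean(extent) + den_diff / max(mean(density), 1e-12)
  best <- which.max(rel)
  if (rel[best] < min_contrast) return(structure(NA_real_, contrast = rel[best]))
  structure(wrap360(best - 1), contrast = rel[best])
}

#' Simulated blinded observer
#'
#' Draws observer readings around the true orientation from a von Mises
#' distribution with concentration `noise_kappa`: `kappa = Inf` is a perfect
#' observer, `kappa = 0` an uninformative one (uniform angles).  Used to
#' exercise the decoding and averaging machinery at configurable observer
#' reliability; real inter-observer noise has no empirical anchor here.
#'
#' @param true_angle_deg true orientation, degrees.
#' @param noise_kappa observer concentration, >= 0 (may be `Inf`).
#' @param n number of readings.
#' @return numeric vector of `n` angles in \[0, 360).
#' @export
simulated_observer <- function(true_angle_deg, noise_kappa, n = 1) {
  stopifnot(noise_kappa >= 0)
  rvonmises(n, true_angle_deg, noise_kappa)
}

#' Average observer angles on the circle
#'
#' Circular mean of the decoded observer readings (angle of the summed unit
#' vectors).  Antipodal or balanced readings have a vanishing resultant and
#' no defined mean: the result is `NA` flagged `ambiguous`.
#'
#' @param angles_deg observer angles, degrees (at least one).
#' @return mean angle in \[0, 360), or `NA` with attribute
#'   `ambiguous = TRUE` when the resultant is numerically zero.
#' @examples
#' average_observers(c(350, 10))  # 0, not 180
#' @export
average_observers <- function(angles_deg) {
  if (length(angles_deg) < 1L) stop("need at least one angle")
  res <- circ_resultant(angles_deg)
  if (res$r < 1e-9) {
    warning("zero resultant: observer angles are antipodal/balanced")
    return(structure(NA_real_, ambiguous = TRUE))
  }
  structure(res$mean_deg, ambiguous = FALSE)
}

#' Run the blinded orientation protocol on a rendered dish
#'
#' For each non-excluded explant of a segmented dish: crop a round field,
#' rotate it by an independent random angle, measure the orientation on the
#' rotated image with the automated morphology surrogate (re-segmenting the
#' blinded crop), optionally add simulated noisy observers, decode by
#' reversing the rotation, and average on the circle.
#'
#' @param dish result of [render_dish()] (or a list with `image`).
#' @param seg [segment_explants()] result for that image.
#' @param n_observers number of simulated observers added to the surrogate
#'   (0 = surrogate only).
#' @param observer_kappa von Mises concentration of simulated observers.
#' @param rng_seed seed for rotations and observer noise.
#' @return data frame of class `orientation_records`: `explant_id`,
#'   `method`, `applied_rotation_deg`, `observer_angles_deg`
#'   (semicolon-separated decoded readings), `mean_orientation_deg`.
#' @export
orient_explants <- function(dish, seg, n_observers = 0, observer_kappa = 20,
                            rng_seed = NULL) {
  stopifnot(inherits(seg, "segmentation_result"))
  img <- dish$image
  px <- pixel_matrix(img)
  rows <- list()
  with_seed(rng_seed, {
    for (p in seg$pairs) {
      if (p$flags$excluded) next
      hf <- tryCatch(fit_ellipse(p$halo), error = function(e) NULL)
      if (is.null(hf)) next
      ctr <- round(hf$center)
      rad <- ceiling(max(sqrt(rowSums(sweep(p$halo$vertices, 2,
                                            hf$center)^2)))) + 6
      rad <- min(rad,
                 ctr[1], nrow(px) - 1 - ctr[1],
                 ctr[2], ncol(px) - 1 - ctr[2])
      br <- blind_rotate(img, center = ctr, radius = rad)
      blind_seg <- tryCatch(
        segment_explants(br$image, polarity = img$polarity),
        warning = function(w) NULL, error = function(e) NULL)
      meas <- NA_real_
      if (!is.null(blind_seg) && length(blind_seg$pairs) >= 1) {
        bp <- blind_seg$pairs[[which.max(vapply(
          blind_seg$pairs, function(q) contour_area(q$halo), 1))]]
        if (!is.null(bp$core))
          meas <- morphology_orientation(br$image, bp$halo, bp$core)
      }
      decoded <- decode_orientation(meas, br$applied_rotation_deg)
      obs <- decoded
      method <- "morphology-based"
      if (n_observers > 0 && !is.na(meas)) {
        # observers see the rotated image; their readings decode independently
        sim <- simulated_observer(meas, observer_kappa, n_observers)
        obs <- c(decoded, decode_orientation(sim, br$applied_rotation_deg))
        method <- "morphology+simulated-observer"
      }
      mean_o <- if (all(is.na(obs))) NA_real_
                else as.numeric(average_observers(obs[!is.na(obs)]))
      rows[[length(rows) + 1L]] <- data.frame(
        explant_id = p$explant_id, method = method,
        applied_rotation_deg = br$applied_rotation_deg,
        observer_angles_deg = paste(round(obs, 3), collapse = ";"),
        mean_orientation_deg = mean_o)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(explant_id = integer(), method = character(),
               applied_rotation_deg = numeric(),
               observer_angles_deg = character(),
               mean_orientation_deg = numeric())
  class(out) <- c("orientation_records", "data.frame")
  out
}
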