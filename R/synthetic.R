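# Synthetic explant-dish generator.
#
# Renders dishes of ganglion explants whose radial neurite outgrowth is
# asymmetric.  The halo boundary is an OFFSET ELLIPSE: semi-major
# alpha = core_radius + base_neurite_length along the orientation axis,
# center displaced by delta = amplitude * alpha along that axis, semi-minor
# alpha * (1 - 0.45 * amplitude).  The core sits at the origin of the
# neurites, i.e. offset from the halo-ellipse center along the major axis
# (and only the major axis), which is exactly the geometry the asymmetry
# index measures: ground truth is index = 100 * amplitude.  To first order
# the implied neurite-length profile is the cosine modulation
# L(theta) ~ L0 * (1 + amplitude * cos(theta - theta0)); the second-harmonic
# (elongation) component is what pins the halo's major axis to the
# orientation axis, as in real halos, where elongation and core offset
# co-occur.  A pure first-harmonic (limacon) profile would instead yield a
# near-circular moment ellipse whose axis is perpendicular to the offset,
# and an index of ~0 at any amplitude.
#
# The short-neurite side is rendered denser and with club-like endings,
# matching the morphology blinded observers score; the long side is sparser.
# All randomness flows from a single dish seed through documented child
# streams, so renders are bit-reproducible.

#' Construct an image field
#'
#' Light container for a 2D grayscale raster.  Pixels are stored with
#' dim1 = x (rightward) and dim2 = y (downward), 0-based coordinates, the
#' same layout `EBImage` uses.
#'
#' @param pixels numeric matrix of nonnegative intensities.
#' @param pixel_size physical length per pixel (arbitrary units; default 1).
#' @param polarity `"bright_on_dark"` (vital-dye-like) or `"dark_on_light"`
#'   (silver-stain-like).
#' @return object of class `image_field`.
#' @export
image_field <- function(pixels, pixel_size = 1,
                        polarity = c("bright_on_dark", "dark_on_light")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(pixels), all(is.finite(pixels)))
  structure(list(pixels = pixels, pixel_size = pixel_size, polarity = polarity),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("image_field %d x %d px (%s), intensity [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$polarity,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Parameters of a single synthetic explant
#'
#' Describes one explant: a bright core disk surrounded by radial neurites
#' reaching out to an offset-ellipse halo boundary.  The halo ellipse has
#' semi-major `core_radius + base_neurite_length` along the orientation
#' axis and its center is displaced from the core by `asymmetry_amplitude`
#' times the semi-major length, so the true asymmetry index equals
#' `100 * asymmetry_amplitude` and neurite length varies with angle
#' approximately as `base_neurite_length * (1 + asymmetry_amplitude *
#' cos(theta - orientation_deg))`.  `orientation_deg` is the direction of
#' the LONGEST neurites (degrees, counterclockwise from +x, y up).  The
#' short side is drawn denser (`density_contrast` thins the long side) and
#' carries club-like ending disks; both cues mimic the tightly packed,
#' club-ended short side seen in stained explants.
#'
#' @param core_radius core disk radius, px.
#' @param base_neurite_length mean neurite length, px.
#' @param asymmetry_amplitude fractional length modulation, in \[0, 1).  An
#'   amplitude of 1 (halo on one side only) is disallowed: the halo must
#'   surround the core.
#' @param orientation_deg direction of the longest neurites, degrees.
#' @param neurite_count number of neurites before density thinning (>= 8).
#' @param length_jitter_cv coefficient of variation of per-neurite length.
#' @param density_contrast fraction in \[0, 1\] by which neurite density is
#'   reduced on the long side.
#' @param club_ending_radius radius of ending disks on the short side, px
#'   (0 disables).
#' @param core_intensity,neurite_intensity rendered intensities in \[0, 1\].
#' @param center_xy optional (x, y) center in dish coordinates, px.
#' @return object of class `explant_params`.
#' @export
explant_params <- function(core_radius = 28,
                           base_neurite_length = 90,
                           asymmetry_amplitude = 0.35,
                           orientation_deg = 0,
                           neurite_count = 240,
                           length_jitter_cv = 0.08,
                           density_contrast = 0.5,
                           club_ending_radius = 2.5,
                           core_intensity = 1,
                           neurite_intensity = 0.55,
                           center_xy = NULL) {
  if (asymmetry_amplitude < 0 || asymmetry_amplitude >= 1)
    stop("asymmetry_amplitude must be in [0, 1): the halo must fully surround the core")
  if (neurite_count < 8) stop("neurite_count must be >= 8")
  stopifnot(core_radius > 0, base_neurite_length > 0, length_jitter_cv >= 0,
            density_contrast >= 0, density_contrast <= 1,
            club_ending_radius >= 0)
  structure(list(
    core_radius = core_radius,
    base_neurite_length = base_neurite_length,
    asymmetry_amplitude = asymmetry_amplitude,
    orientation_deg = wrap360(orientation_deg),
    neurite_count = as.integer(neurite_count),
    length_jitter_cv = length_jitter_cv,
    density_contrast = density_contrast,
    club_ending_radius = club_ending_radius,
    core_intensity = core_intensity,
    neurite_intensity = neurite_intensity,
    center_xy = center_xy
  ), class = "explant_params")
}

#' @noRd
#' Halo-boundary radius from the core center at polar angle `theta` (radians,
#' measured from the orientation axis): the positive root of the offset
#' ellipse with semi-axes (alpha, beta) centered `delta` along the axis.
halo_boundary_radius <- function(theta, alpha, beta, delta) {
  ct <- cos(theta); st <- sin(theta)
  A <- ct^2 / alpha^2 + st^2 / beta^2
  B <- -2 * ct * delta / alpha^2
  C <- delta^2 / alpha^2 - 1
  (-B + sqrt(pmax(B^2 - 4 * A * C, 0))) / (2 * A)
}

#' @noRd
halo_shape <- function(p) {
  alpha <- p$core_radius + p$base_neurite_length
  list(alpha = alpha,
       beta = alpha * (1 - 0.45 * p$asymmetry_amplitude),
       delta = p$asymmetry_amplitude * alpha)
}

#' @noRd
#' Conservative upper bound on the halo radius of an explant, px.
halo_max_radius <- function(p) {
  sh <- halo_shape(p)
  jit <- 1 + 3.5 * p$length_jitter_cv
  p$core_radius + (sh$alpha + sh$delta - p$core_radius) * jit +
    p$club_ending_radius + 3
}

#' @noRd
#' Paint a filled disk onto canvas (max-combine).  Center 0-based.
draw_disk <- function(canvas, cx, cy, r, value) {
  nx <- nrow(canvas); ny <- ncol(canvas)
  xs <- max(0, floor(cx - r)):min(nx - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(ny - 1, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(canvas)
  dx2 <- (xs - cx)^2
  for (y in ys) {
    sel <- xs[dx2 + (y - cy)^2 <= r^2]
    if (length(sel)) {
      idx <- cbind(sel + 1L, y + 1L)
      canvas[idx] <- pmax(canvas[idx], value)
    }
  }
  canvas
}

#' @noRd
#' Max-combine a tile into canvas with the tile's first pixel at 0-based
#' canvas coordinates (x0, y0); out-of-canvas parts are clipped.
blit_max <- function(canvas, tile, x0, y0) {
  nx <- nrow(canvas); ny <- ncol(canvas)
  tx <- nrow(tile); ty <- ncol(tile)
  xs <- max(1, x0 + 1):min(nx, x0 + tx)
  ys <- max(1, y0 + 1):min(ny, y0 + ty)
  if (!length(xs) || !length(ys)) return(canvas)
  canvas[xs, ys] <- pmax(canvas[xs, ys],
                         tile[xs - x0, ys - y0, drop = FALSE])
  canvas
}

#' @noRd
#' Paint points sampled at sub-pixel spacing onto canvas (max-combine).
draw_points <- function(canvas, px, py, value) {
  nx <- nrow(canvas); ny <- ncol(canvas)
  ix <- round(px); iy <- round(py)
  ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  if (any(ok)) {
    idx <- cbind(ix[ok] + 1L, iy[ok] + 1L)
    canvas[idx] <- pmax(canvas[idx], value)
  }
  canvas
}

#' @noRd
#' Render one explant onto an existing canvas.  Returns list(canvas, truth).
#' Assumes the RNG state has been set by the caller (child stream).
draw_explant <- function(canvas, p, cx, cy, explant_id = 1L) {
  th0 <- deg2rad(p$orientation_deg)
  n <- p$neurite_count
  base_ang <- (seq_len(n) - 1) / n * 2 * pi +
    stats::runif(n, -pi / n, pi / n)
  cosd <- cos(base_ang - th0)
  # density thinning on the long-neurite side; a low-discrepancy (golden
  # ratio) sequence spreads the dropped neurites evenly around the rim so
  # thinning changes density without carving clustered gaps into the halo
  u_thin <- (seq_len(n) * 0.6180339887498949 + stats::runif(1)) %% 1
  keep <- u_thin >= p$density_contrast * pmax(cosd, 0)
  sh <- halo_shape(p)
  rmin <- min(halo_boundary_radius(seq(0, 2 * pi, length.out = 361),
                                   sh$alpha, sh$beta, sh$delta))
  if (rmin <= p$core_radius)
    stop("asymmetry_amplitude too large: core would touch the halo boundary")
  len <- halo_boundary_radius(base_ang - th0, sh$alpha, sh$beta, sh$delta) -
    p$core_radius
  if (p$length_jitter_cv > 0)
    len <- len * pmax(0.1, 1 + p$length_jitter_cv * stats::rnorm(n))
  max_r <- 0
  all_px <- vector("list", n); all_py <- vector("list", n)
  clubs <- NULL
  for (i in which(keep)) {
    r_out <- p$core_radius + len[i]
    rr <- seq(p$core_radius * 0.8, r_out, by = 0.5)
    # slight lateral wobble so neurites are not perfectly straight
    wob <- 0.8 * sin(rr / 25 + stats::runif(1, 0, 2 * pi)) *
      (rr - rr[1]) / max(r_out - rr[1], 1)
    ca <- cos(base_ang[i]); sa <- sin(base_ang[i])
    sx <- cx + rr * ca - wob * sa
    sy <- cy - (rr * sa + wob * ca)   # raster y runs downward
    # two parallel sub-pixel strands give the neurite ~2 px caliber and keep
    # the rasterized line 4-connected across diagonal steps
    all_px[[i]] <- c(sx, sx + 0.71 * sa)
    all_py[[i]] <- c(sy, sy + 0.71 * ca)
    tip_r <- r_out
    if (p$club_ending_radius > 0 && cosd[i] < 0) {
      clubs <- rbind(clubs, c(sx[length(rr)], sy[length(rr)]))
      tip_r <- r_out + p$club_ending_radius
    }
    max_r <- max(max_r, tip_r)
  }
  canvas <- draw_points(canvas, unlist(all_px), unlist(all_py),
                        p$neurite_intensity)
  for (k in seq_len(NROW(clubs)))
    canvas <- draw_disk(canvas, clubs[k, 1], clubs[k, 2],
                        p$club_ending_radius,
                        min(1, p$neurite_intensity * 1.25))
  canvas <- draw_disk(canvas, cx, cy, p$core_radius, p$core_intensity)
  truth <- data.frame(
    explant_id = explant_id,
    center_x = cx, center_y = cy,
    orientation_deg = p$orientation_deg,
    asymmetry_amplitude = p$asymmetry_amplitude,
    true_asymmetry_pct = 100 * p$asymmetry_amplitude,
    core_radius = p$core_radius,
    base_neurite_length = p$base_neurite_length,
    max_halo_radius = max_r,
    touches_dish_edge = FALSE,
    merged_with_neighbor = FALSE
  )
  list(canvas = canvas, truth = truth)
}

#' Render a single synthetic explant
#'
#' Draws one explant (core disk plus radial neurites) on a fresh square
#' canvas and returns the image together with its ground-truth record.
#' Rendering is deterministic given `rng_seed`.
#'
#' @param params an [explant_params()] object.
#' @param image_size side length in px; by default just large enough to hold
#'   the halo.  Images that cannot contain the halo bounding box are rejected.
#' @param rng_seed integer seed (NULL uses the current RNG stream).
#' @param noise_sd additive Gaussian read-noise standard deviation (0 for a
#'   noise-free render).
#' @param background background intensity level.
#' @param bg_gradient peak-to-peak amplitude of a linear background gradient
#'   across the field (0 disables).
#' @param polarity `"bright_on_dark"` renders the stain bright; with
#'   `"dark_on_light"` the intensity scale is inverted, emulating silver
#'   staining.
#' @return list with `image` (an [image_field()]) and `ground_truth`
#'   (one-row data frame: true orientation, amplitude, geometry).
#' @examples
#' ex <- render_explant(explant_params(asymmetry_amplitude = 0.3),
#'                      rng_seed = 7, noise_sd = 0)
#' dim(ex$image$pixels)
#' @export
render_explant <- function(params, image_size = NULL, rng_seed = NULL,
                           noise_sd = 0.01, background = 0.06,
                           bg_gradient = 0,
                           polarity = c("bright_on_dark", "dark_on_light")) {
  stopifnot(inherits(params, "explant_params"))
  polarity <- match.arg(polarity)
  rmax <- halo_max_radius(params)
  need <- 2 * ceiling(rmax) + 9
  if (is.null(image_size)) image_size <- need
  if (image_size < need)
    stop(sprintf("image_size %d too small for halo bounding box (need >= %d)",
                 image_size, need))
  with_seed(rng_seed, {
    canvas <- matrix(0, image_size, image_size)
    c0 <- (image_size - 1) / 2
    dr <- draw_explant(canvas, params, c0, c0, explant_id = 1L)
    img <- finish_render(dr$canvas, noise_sd, background, bg_gradient, polarity)
    list(image = img, ground_truth = dr$truth)
  })
}

#' @noRd
#' Apply background, gradient, noise and polarity; clamp to [0, 1].
finish_render <- function(canvas, noise_sd, background, bg_gradient, polarity) {
  nx <- nrow(canvas)
  px <- pmax(canvas, background)
  if (bg_gradient > 0)
    px <- px + bg_gradient * (row(px) / nx - 0.5)
  if (noise_sd > 0)
    px <- px + stats::rnorm(length(px), sd = noise_sd)
  px <- pmin(pmax(px, 0), 1)
  if (polarity == "dark_on_light") px <- 1 - px
  image_field(px, polarity = polarity)
}

#' Configuration of a synthetic culture dish
#'
#' Describes one dish: its radius, the explants (or dissociated neurons) it
#' contains, and the dish-level co-orientation model.  Per-explant long-
#' neurite orientations are drawn from a von Mises distribution centred on
#' `dish_mean_orientation_deg` with concentration `coorientation_kappa`;
#' `kappa = 0` gives uniform (unoriented) dishes, large kappa gives strongly
#' co-oriented dishes.  Each dish draws its own mean independently (when
#' `dish_mean_orientation_deg` is NULL), reflecting the observation that
#' orientation is not consistent from one dish to the next.
#'
#' @param n_explants number of explants (or clusters) in the dish.
#' @param scenario `"explants"`, `"dissociated"` (a carpet of independent
#'   short neurites from single cells, no co-orientation), `"reaggregated"`
#'   (multi-lobed re-aggregated clusters with explant-style halos) or
#'   `"mixed"` (one explant amid dissociated cells).
#' @param dish_radius dish radius, px; NULL chooses the smallest dish that
#'   fits `n_explants` non-overlapping halos.
#' @param dish_mean_orientation_deg dish-level mean orientation; NULL draws
#'   it uniformly at random per dish.
#' @param coorientation_kappa von Mises concentration of per-explant
#'   orientations about the dish mean (>= 0).
#' @param explant explant template, an [explant_params()] object applied to
#'   every explant (orientation and center are overridden per explant).
#' @param rng_seed integer seed; the dish image and ground truth are a pure
#'   function of the full configuration.
#' @param edge_margin exclusion margin from the dish boundary, px: explants
#'   whose halo can reach within this margin of the edge are flagged.
#' @param min_separation minimal center-to-center distance; NULL defaults to
#'   non-overlapping halos (sum of max halo radii plus clearance).  Smaller
#'   values allow overlapping halos, which are then flagged as merged.
#' @param noise_sd,background,bg_gradient,polarity passed to the renderer.
#' @param n_cells number of dissociated neurons (dissociated/mixed
#'   scenarios); NULL gives a dense plexus-forming carpet of about one cell
#'   per 300 px^2 of dish area (a plexus-forming carpet).
#' @return object of class `dish_config`.
#' @export
dish_config <- function(n_explants = 8,
                        scenario = c("explants", "dissociated",
                                     "reaggregated", "mixed"),
                        dish_radius = NULL,
                        dish_mean_orientation_deg = NULL,
                        coorientation_kappa = 20,
                        explant = explant_params(),
                        rng_seed = 1,
                        edge_margin = 40,
                        min_separation = NULL,
                        noise_sd = 0.01,
                        background = 0.06,
                        bg_gradient = 0,
                        polarity = "bright_on_dark",
                        n_cells = NULL) {
  scenario <- match.arg(scenario)
  stopifnot(coorientation_kappa >= 0, n_explants >= 1)
  rmax <- halo_max_radius(explant)
  if (is.null(min_separation)) min_separation <- 2 * rmax + 30
  if (is.null(dish_radius)) {
    # ring layout bound: n points on a ring, adjacent chords >= min_separation
    inner <- if (n_explants == 1) 0
             else 1.25 * min_separation / (2 * sin(pi / max(n_explants, 2)))
    dish_radius <- ceiling(inner + rmax + edge_margin + 10)
  }
  structure(list(
    n_explants = as.integer(n_explants), scenario = scenario,
    dish_radius = dish_radius,
    dish_mean_orientation_deg = dish_mean_orientation_deg,
    coorientation_kappa = coorientation_kappa,
    explant = explant, rng_seed = rng_seed,
    edge_margin = edge_margin, min_separation = min_separation,
    noise_sd = noise_sd, background = background,
    bg_gradient = bg_gradient, polarity = polarity,
    n_cells = if (is.null(n_cells)) NULL else as.integer(n_cells)
  ), class = "dish_config")
}

#' @noRd
#' Sample n centers in a disk of radius `rad` with pairwise distance >=
#' `min_sep`, by dart throwing with restarts.  Raises a layout error on
#' failure.
layout_centers <- function(n, rad, min_sep, tries = 400) {
  if (n == 1) return(cbind(0, 0))
  for (t in seq_len(tries)) {
    pts <- matrix(NA_real_, n, 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (k in seq_len(120)) {
        a <- stats::runif(1, 0, 2 * pi); r <- rad * sqrt(stats::runif(1))
        cand <- c(r * cos(a), r * sin(a))
        if (i == 1 ||
            all(sqrt(rowSums((pts[seq_len(i - 1), , drop = FALSE] -
                              matrix(cand, i - 1, 2, byrow = TRUE))^2)) >=
                min_sep)) {
          pts[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pts)
  }
  # dart throwing failed (tight packing): fall back to a jittered ring
  for (t in seq_len(200)) {
    a0 <- stats::runif(1, 0, 2 * pi)
    jit_a <- stats::runif(n, -0.25, 0.25) * 2 * pi / n
    jit_r <- stats::runif(n, 0.9, 1) * rad
    th <- a0 + (seq_len(n) - 1) * 2 * pi / n + jit_a
    pts <- cbind(jit_r * cos(th), jit_r * sin(th))
    if (min(stats::dist(pts)) >= min_sep) return(pts)
  }
  stop("layout error: could not place ", n,
       " explants with separation ", round(min_sep),
       " in a dish of radius ", round(rad))
}

#' Render a synthetic culture dish
#'
#' Draws all explants (or dissociated neurons / re-aggregated clusters) of a
#' [dish_config()] onto one dish-sized canvas and returns the image together
#' with the per-explant ground truth table.  The same configuration always
#' yields a bit-identical image and table.
#'
#' Ground-truth flags mirror the inclusion rules used downstream: explants
#' whose halo can reach within `edge_margin` of the dish boundary are flagged
#' `touches_dish_edge`, and pairs closer than the sum of their maximal halo
#' radii are flagged `merged_with_neighbor`.
#'
#' @param config a [dish_config()].
#' @return list with `image` (an [image_field()]), `ground_truth` (data
#'   frame, one row per explant; for dissociated scenarios one row per cell
#'   field) and `config`.
#' @export
render_dish <- function(config) {
  stopifnot(inherits(config, "dish_config"))
  with_seed(config$rng_seed, {
    R <- config$dish_radius
    size <- 2 * R + 1
    canvas <- matrix(0, size, size)
    c0 <- R  # dish center, 0-based coords
    mu <- config$dish_mean_orientation_deg
    if (is.null(mu)) mu <- stats::runif(1, 0, 360)
    truths <- list()

    if (config$scenario %in% c("explants", "reaggregated", "mixed")) {
      n_exp <- if (config$scenario == "mixed") 1L else config$n_explants
      rmax <- halo_max_radius(config$explant)
      usable <- R - config$edge_margin - rmax
      if (usable <= 0) stop("layout error: dish too small for explant halos")
      centers <- layout_centers(n_exp, usable, config$min_separation)
      oris <- if (config$coorientation_kappa == 0)
        stats::runif(n_exp, 0, 360)
      else rvonmises(n_exp, mu, config$coorientation_kappa)
      for (i in seq_len(n_exp)) {
        p <- config$explant
        p$orientation_deg <- oris[i]
        cxi <- round(c0 + centers[i, 1]); cyi <- round(c0 + centers[i, 2])
        # each explant renders on its own tile (then max-blitted), so the
        # full dish canvas is not copied per drawing call
        side <- 2L * ceiling(halo_max_radius(p)) + 9L
        tc <- (side - 1) / 2
        with_seed(child_seed(config$rng_seed, i), {
          tile <- matrix(0, side, side)
          if (config$scenario == "reaggregated")
            tile <- draw_lobed_core(tile, p, tc, tc)
          dr <- draw_explant(tile, p, tc, tc, explant_id = i)
        })
        canvas <- blit_max(canvas, dr$canvas, cxi - tc, cyi - tc)
        dr$truth$center_x <- cxi; dr$truth$center_y <- cyi
        truths[[i]] <- dr$truth
      }
      gt <- do.call(rbind, truths)
      # exclusion flags from layout geometry
      d_center <- sqrt((gt$center_x - c0)^2 + (gt$center_y - c0)^2)
      gt$touches_dish_edge <- d_center + gt$max_halo_radius >
        R - config$edge_margin
      if (n_exp > 1) {
        for (i in seq_len(n_exp - 1)) for (j in (i + 1):n_exp) {
          dij <- sqrt((gt$center_x[i] - gt$center_x[j])^2 +
                      (gt$center_y[i] - gt$center_y[j])^2)
          if (dij < gt$max_halo_radius[i] + gt$max_halo_radius[j]) {
            gt$merged_with_neighbor[c(i, j)] <- TRUE
          }
        }
      }
    } else gt <- NULL

    if (config$scenario %in% c("dissociated", "mixed")) {
      keep_clear <- if (config$scenario == "mixed")
        cbind(c0, c0, halo_max_radius(config$explant) + 15) else NULL
      n_cells <- config$n_cells
      if (is.null(n_cells))
        n_cells <- round(pi * (R - config$edge_margin)^2 / 300)
      with_seed(child_seed(config$rng_seed, 9973L), {
        canvas <- draw_dissociated(canvas, c0, R - config$edge_margin,
                                   n_cells, keep_clear)
      })
      cell_row <- data.frame(
        explant_id = NA_integer_, center_x = c0, center_y = c0,
        orientation_deg = NA_real_, asymmetry_amplitude = NA_real_,
        true_asymmetry_pct = NA_real_,
        core_radius = NA_real_, base_neurite_length = NA_real_,
        max_halo_radius = NA_real_, touches_dish_edge = FALSE,
        merged_with_neighbor = FALSE)
      gt <- rbind(gt, cell_row)
    }

    # dish rim: zero outside the dish so the boundary is visible
    xs <- matrix(0:(size - 1), size, size)
    out <- (xs - c0)^2 + (t(xs) - c0)^2 > R^2
    img <- with_seed(child_seed(config$rng_seed, 7919L),
      finish_render(canvas, config$noise_sd, config$background,
                    config$bg_gradient, config$polarity))
    img$pixels[out] <- if (config$polarity == "dark_on_light") 1 else 0
    gt$dish_mean_orientation_deg <- mu
    gt$coorientation_kappa <- config$coorientation_kappa
    list(image = img, ground_truth = gt, config = config)
  })
}

#' @noRd
#' Multi-lobed core for re-aggregated clusters: 2-4 overlapping disks.
draw_lobed_core <- function(canvas, p, cx, cy) {
  n_lobe <- sample(2:4, 1)
  for (k in seq_len(n_lobe)) {
    a <- stats::runif(1, 0, 2 * pi)
    d <- stats::runif(1, 0.3, 0.75) * p$core_radius
    canvas <- draw_disk(canvas, cx + d * cos(a), cy + d * sin(a),
                        p$core_radius * stats::runif(1, 0.5, 0.8),
                        p$core_intensity)
  }
  canvas
}

#' @noRd
#' Carpet of dissociated neurons: small somata extending a few short,
#' gently curved neurites at uniformly random orientations.
draw_dissociated <- function(canvas, c0, rad, n_cells, keep_clear = NULL) {
  for (i in seq_len(n_cells)) {
    repeat {
      a <- stats::runif(1, 0, 2 * pi); r <- rad * sqrt(stats::runif(1))
      cx <- c0 + r * cos(a); cy <- c0 + r * sin(a)
      if (is.null(keep_clear) ||
          all(sqrt((cx - keep_clear[, 1])^2 + (cy - keep_clear[, 2])^2) >
              keep_clear[, 3])) break
    }
    canvas <- draw_disk(canvas, cx, cy, stats::runif(1, 2.5, 4), 0.9)
    for (k in seq_len(sample(1:3, 1))) {
      th <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 30, 70)
      curv <- stats::runif(1, -0.008, 0.008)
      tt <- seq(0, len, by = 0.5)
      ang <- th + curv * tt
      px <- cx + cumsum(c(0, diff(tt)) * cos(ang))
      py <- cy + cumsum(c(0, diff(tt)) * sin(ang))
      canvas <- draw_points(canvas, c(px, px - 0.71 * sin(th)),
                            c(py, py + 0.71 * cos(th)), 0.5)
    }
  }
  canvas
}

#' Write a rendered dish to disk
#'
#' Persists the image as 16-bit grayscale TIFF (optionally PNG), the ground
#' truth as CSV, and the configuration as YAML, so a dish can be regenerated
#' or re-analysed without the generator.
#'
#' @param dish result of [render_dish()] (or [render_explant()]; the ground
#'   truth table is written as-is).
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @param format `"tiff"` or `"png"`.
#' @return invisibly, the paths written.
#' @export
write_dish <- function(dish, dir, name = "dish", format = c("tiff", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".", if (format == "tiff") "tif" else "png"))
  EBImage::writeImage(EBImage::Image(dish$image$pixels), img_path,
                      bits.per.sample = 16L)
  gt_path <- file.path(dir, paste0(name, "_ground_truth.csv"))
  utils::write.csv(dish$ground_truth, gt_path, row.names = FALSE)
  paths <- c(image = img_path, ground_truth = gt_path)
  if (!is.null(dish$config)) {
    cfg <- dish$config
    cfg$explant <- unclass(cfg$explant)
    cfg_path <- file.path(dir, paste0(name, "_config.yaml"))
    yaml::write_yaml(unclass(cfg), cfg_path)
    paths <- c(paths, config = cfg_path)
  }
  invisible(paths)
}

#' Read an image file as an image field
#'
#' Reads a TIFF or PNG grayscale image into the package's raster convention
#' (dim1 = x, dim2 = y downward).  Multi-channel images are averaged to
#' grayscale.
#'
#' @param path image file path.
#' @param polarity stain polarity; `"auto"` detects it from the intensity
#'   distribution (background is assumed to be the majority phase).
#' @return an [image_field()].
#' @export
read_image_field <- function(path, polarity = c("auto", "bright_on_dark",
                                                "dark_on_light")) {
  polarity <- match.arg(polarity)
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  if (length(dim(px)) > 2) px <- apply(px, c(1, 2), mean)
  if (polarity == "auto")
    polarity <- if (stats::median(px) > mean(range(px))) "dark_on_light"
                else "bright_on_dark"
  image_field(px, polarity = polarity)
}
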