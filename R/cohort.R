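# Cohort- and dish-level reporting.
#
# Ties the stages together: per-explant asymmetry measurements are pooled
# into a prevalence histogram with threshold fractions and area scattergram
# correlations, and per-dish orientations are tested for co-orientation with
# the Rayleigh test.  Dishes are treated as independent units: each draws
# its own mean orientation, so co-orientation is a within-dish claim only.

#' Summarize an asymmetry cohort
#'
#' Builds the cohort report from measurement rows (optionally from several
#' dishes): a histogram of the asymmetry index, the fraction of explants at
#' or above each threshold, the mode bin, rank correlations of asymmetry
#' with core and halo area, and per-dish Rayleigh co-orientation tests when
#' orientations are supplied.
#'
#' @param measurements a [measure_dish()] data frame, or several such tables
#'   row-bound with a `dish_id` column.
#' @param orientations optional [orient_explants()] records (or any data
#'   frame with `mean_orientation_deg`, optionally `dish_id`) for the
#'   per-dish Rayleigh tests.
#' @param thresholds asymmetry thresholds (percent) for the prevalence
#'   fractions; default 15.
#' @param bin_width histogram bin width in asymmetry points (default 5).
#' @param cor_method `"spearman"` (default; the area scattergrams are not
#'   Gaussian) or `"pearson"`.
#' @return object of class `cohort_summary`; an empty-cohort sentinel (with
#'   `n_measured = 0`) when every explant is excluded.
#' @export
summarize_cohort <- function(measurements, orientations = NULL,
                             thresholds = 15, bin_width = 5,
                             cor_method = c("spearman", "pearson")) {
  cor_method <- match.arg(cor_method)
  m <- as.data.frame(measurements)
  n_total <- nrow(m)
  excl <- m$excluded | is.na(m$asymmetry_pct)
  ok <- m[!excl, , drop = FALSE]
  reasons <- table(m$reason[excl], useNA = "no")
  if (nrow(ok) == 0) {
    return(structure(list(n_explants = n_total, n_measured = 0L,
                          n_excluded = sum(excl),
                          exclusion_reasons = reasons, empty = TRUE),
                     class = "cohort_summary"))
  }
  breaks <- seq(0, 100, by = bin_width)
  h <- graphics::hist(pmin(ok$asymmetry_pct, 100 - 1e-9), breaks = breaks,
                      plot = FALSE)
  frac <- vapply(thresholds, function(t) mean(ok$asymmetry_pct >= t), 1.0)
  names(frac) <- as.character(thresholds)
  corr <- function(xvar) {
    if (all(is.na(ok[[xvar]]))) return(list(estimate = NA_real_, p = NA_real_))
    ct <- suppressWarnings(
      stats::cor.test(ok$asymmetry_pct, ok[[xvar]], method = cor_method))
    list(estimate = unname(ct$estimate), p = ct$p.value)
  }
  ray <- NULL
  if (!is.null(orientations) && nrow(orientations) > 0) {
    o <- as.data.frame(orientations)
    o <- o[!is.na(o$mean_orientation_deg), , drop = FALSE]
    if (nrow(o) > 0) {
      did <- if ("dish_id" %in% names(o)) o$dish_id else rep(1L, nrow(o))
      ray <- do.call(rbind, lapply(split(o$mean_orientation_deg, did),
        function(a) {
          rt <- suppressWarnings(rayleigh_test(a))
          data.frame(n = rt$n, r = rt$r,
                     mean_direction_deg = rt$mean_direction_deg,
                     p_value = rt$p_value)
        }))
      ray <- cbind(dish_id = rownames(ray), ray)
      rownames(ray) <- NULL
    }
  }
  structure(list(
    n_explants = n_total,
    n_measured = nrow(ok),
    n_excluded = sum(excl),
    exclusion_reasons = reasons,
    histogram = data.frame(bin_low = h$breaks[-length(h$breaks)],
                           bin_high = h$breaks[-1], mid = h$mids,
                           count = h$counts),
    fraction_at_least = frac,
    mode_bin_mid = h$mids[which.max(h$counts)],
    correlations = list(core_area = corr("core_area"),
                        halo_area = corr("halo_area"),
                        method = cor_method),
    rayleigh = ray,
    empty = FALSE
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("cohort_summary: %d explants (%d measured, %d excluded)\n",
              x$n_explants, x$n_measured, x$n_excluded))
  if (isTRUE(x$empty)) { cat("  (empty cohort)\n"); return(invisible(x)) }
  for (t in names(x$fraction_at_least))
    cat(sprintf("  fraction with asymmetry >= %s%%: %.3f\n",
                t, x$fraction_at_least[[t]]))
  cat(sprintf("  mode bin midpoint: %.1f%%\n", x$mode_bin_mid))
  cat(sprintf("  asymmetry vs core area: %s = %.3f (p = %.3g)\n",
              x$correlations$method, x$correlations$core_area$estimate,
              x$correlations$core_area$p))
  cat(sprintf("  asymmetry vs halo area: %s = %.3f (p = %.3g)\n",
              x$correlations$method, x$correlations$halo_area$estimate,
              x$correlations$halo_area$p))
  if (!is.null(x$rayleigh)) {
    cat("  per-dish Rayleigh co-orientation:\n")
    print(x$rayleigh)
  }
  invisible(x)
}

#' Run the full analysis pipeline on a dish
#'
#' simulate (optional) -> segment -> measure -> orient -> Rayleigh ->
#' summarize, fully seeded.  Per-explant failures at any stage become
#' exclusions; the pipeline always returns a complete report.
#'
#' @param x a [dish_config()] (the dish is rendered first) or a rendered
#'   dish / [image_field()].
#' @param out_dir optional directory: when given, all intermediates are
#'   persisted (`measurements.csv`, `orientations.csv`, `rayleigh.csv`,
#'   `cohort_summary.json`, plus the image and ground truth for simulated
#'   dishes).
#' @param orientation_method `"length"` uses the long-neurite direction from
#'   the asymmetry measurement; `"morphology"` runs the blinded
#'   rotation/morphology protocol (slower, exercised in tests).
#' @param n_observers,observer_kappa simulated observers for the blinded
#'   protocol.
#' @param rng_seed seed for every stochastic stage downstream of rendering
#'   (rotations, observers).
#' @param ... passed to [segment_explants()] (e.g. dish geometry).
#' @return list of class `dish_report`: `dish`, `segmentation`,
#'   `measurements`, `orientations`, `rayleigh`, `summary`.
#' @export
run_pipeline <- function(x, out_dir = NULL,
                         orientation_method = c("length", "morphology"),
                         n_observers = 0, observer_kappa = 20,
                         rng_seed = 1, ...) {
  orientation_method <- match.arg(orientation_method)
  dish <- if (inherits(x, "dish_config")) render_dish(x)
          else if (inherits(x, "image_field")) list(image = x,
                                                    ground_truth = NULL)
          else x
  seg_args <- list(...)
  if (!is.null(dish$config) &&
      !any(c("dish_center", "dish_radius") %in% names(seg_args))) {
    R <- dish$config$dish_radius
    seg_args$dish_center <- c(R, R)
    seg_args$dish_radius <- R
    seg_args$edge_margin <- dish$config$edge_margin
  }
  seg <- do.call(segment_explants, c(list(dish$image), seg_args))
  meas <- measure_dish(seg)
  if (orientation_method == "morphology") {
    ori <- orient_explants(dish, seg, n_observers = n_observers,
                           observer_kappa = observer_kappa,
                           rng_seed = rng_seed)
  } else {
    ok <- !meas$excluded & !is.na(meas$long_orientation_deg)
    ori <- data.frame(explant_id = meas$explant_id[ok],
                      method = "length-based",
                      applied_rotation_deg = NA_real_,
                      observer_angles_deg = "",
                      mean_orientation_deg = meas$long_orientation_deg[ok])
  }
  summ <- summarize_cohort(meas, ori)
  report <- structure(list(dish = dish, segmentation = seg,
                           measurements = meas, orientations = ori,
                           rayleigh = summ$rayleigh, summary = summ),
                      class = "dish_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.dish_report <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Persist a dish report bundle
#'
#' Writes measurements, orientations and Rayleigh results as CSV and the
#' cohort summary as JSON (plus image and ground truth for simulated
#' dishes).
#'
#' @param report a `dish_report` from [run_pipeline()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (!is.null(report$dish$ground_truth))
    paths <- write_dish(report$dish, dir)
  p1 <- file.path(dir, "measurements.csv")
  utils::write.csv(as.data.frame(report$measurements), p1, row.names = FALSE)
  p2 <- file.path(dir, "orientations.csv")
  utils::write.csv(as.data.frame(report$orientations), p2, row.names = FALSE)
  paths <- c(paths, measurements = p1, orientations = p2)
  if (!is.null(report$rayleigh)) {
    p3 <- file.path(dir, "rayleigh.csv")
    utils::write.csv(report$rayleigh, p3, row.names = FALSE)
    paths <- c(paths, rayleigh = p3)
  }
  s <- report$summary
  s$exclusion_reasons <- as.list(s$exclusion_reasons)
  p4 <- file.path(dir, "cohort_summary.json")
  jsonlite::write_json(unclass(s), p4, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  paths <- c(paths, summary = p4)
  invisible(paths)
}

#' Histogram of asymmetry prevalence
#'
#' @param summary a `cohort_summary`.
#' @return a ggplot object.
#' @export
plot_asymmetry_histogram <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"), !isTRUE(summary$empty))
  h <- summary$histogram
  ggplot2::ggplot(h, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = h$bin_high[1] - h$bin_low[1],
                      fill = "grey35", colour = "white") +
    ggplot2::labs(x = "neurite length asymmetry (%)", y = "explants") +
    ggplot2::theme_classic()
}

#' Polar diagram of explant orientations
#'
#' Each explant's orientation is drawn as a unit ray from the origin, the
#' usual way co-orientation within a dish is displayed.
#'
#' @param angles_deg orientations in degrees.
#' @return a ggplot object.
#' @export
plot_orientation_polar <- function(angles_deg) {
  df <- data.frame(angle = wrap360(angles_deg))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = angle, xend = angle,
                                       y = 0, yend = 1)) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
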