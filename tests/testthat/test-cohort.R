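mid_explant <- function(...) {
  explant_params(core_radius = 16, base_neurite_length = 48,
                 neurite_count = 130, club_ending_radius = 1.5, ...)
}

test_that("threshold fractions and histogram bookkeeping are exact", {
  m <- data.frame(explant_id = 1:3, asymmetry_pct = c(10, 20, 30),
                  long_orientation_deg = c(0, 10, 20),
                  halo_area = c(1, 2, 3) * 1e4, core_area = c(1, 2, 3) * 1e2,
                  low_confidence = FALSE, excluded = FALSE, reason = NA)
  s <- summarize_cohort(m, thresholds = 15)
  expect_equal(unname(s$fraction_at_least["15"]), 2 / 3)
  expect_equal(sum(s$histogram$count), 3)
  expect_equal(s$n_measured + 0L, 3L)

  # exclusions: counts reconcile and reasons are tabulated
  m2 <- rbind(m, data.frame(explant_id = 4, asymmetry_pct = NA,
                            long_orientation_deg = NA, halo_area = 1e4,
                            core_area = NA, low_confidence = NA,
                            excluded = TRUE, reason = "merged_with_neighbor"))
  s2 <- summarize_cohort(m2)
  expect_equal(s2$n_explants, 4)
  expect_equal(s2$n_measured + s2$n_excluded, 4)
  expect_equal(unname(s2$exclusion_reasons["merged_with_neighbor"]), 1)

  # all excluded: empty sentinel
  m3 <- m2[4, , drop = FALSE]
  s3 <- summarize_cohort(m3)
  expect_true(s3$empty)
  expect_equal(s3$n_measured, 0L)
})

test_that("a 0.35-amplitude cohort is prevalently asymmetric at the oracle mode", {
  n <- 60
  vals <- numeric(n); core_a <- numeric(n); halo_a <- numeric(n)
  for (i in seq_len(n)) {
    ex <- render_explant(mid_explant(asymmetry_amplitude = 0.35,
                                     orientation_deg = (i * 37) %% 360),
                         rng_seed = 2000 + i, noise_sd = 0)
    m <- measure_dish(segment_explants(ex$image))
    vals[i] <- m$asymmetry_pct[1]
    core_a[i] <- m$core_area[1]; halo_a[i] <- m$halo_area[1]
  }
  meas <- data.frame(explant_id = seq_len(n), asymmetry_pct = vals,
                     long_orientation_deg = 0, halo_area = halo_a,
                     core_area = core_a, low_confidence = FALSE,
                     excluded = FALSE, reason = NA)
  s <- summarize_cohort(meas, thresholds = 15)
  expect_gt(unname(s$fraction_at_least["15"]), 0.9)
  # the mode bin contains the analytic expectation for this amplitude
  oracle <- halo_oracle(16, 48, 0.35, 0)$asymmetry_pct
  expect_lte(abs(s$mode_bin_mid - oracle), 5)
})

test_that("a symmetric cohort stays below the prevalence threshold", {
  vals <- vapply(1:20, function(i) {
    ex <- render_explant(mid_explant(asymmetry_amplitude = 0),
                         rng_seed = 3000 + i, noise_sd = 0)
    measure_dish(segment_explants(ex$image))$asymmetry_pct[1]
  }, 1.0)
  expect_lt(mean(vals >= 15), 0.1)
})

test_that("the full pipeline is reproducible and detects co-orientation", {
  cfg <- dish_config(n_explants = 8, coorientation_kappa = 50,
                     explant = mid_explant(asymmetry_amplitude = 0.35),
                     rng_seed = 77)
  r1 <- run_pipeline(cfg, rng_seed = 5)
  expect_s3_class(r1$summary, "cohort_summary")
  expect_lt(r1$rayleigh$p_value[1], 0.05)
  expect_equal(r1$summary$n_measured, 8)

  # byte-identical report CSVs on rerun
  t1 <- withr::local_tempdir(); t2 <- withr::local_tempdir()
  write_report(r1, t1)
  write_report(run_pipeline(cfg, rng_seed = 5), t2)
  for (f in c("measurements.csv", "orientations.csv", "rayleigh.csv")) {
    expect_identical(readLines(file.path(t1, f)),
                     readLines(file.path(t2, f)))
  }
  expect_true(file.exists(file.path(t1, "cohort_summary.json")))
})

test_that("unoriented dishes reject only at the nominal rate", {
  # pipeline-level type I: kappa = 0 dishes, length-based orientations
  rej <- 0; n_dish <- 25
  for (s in seq_len(n_dish)) {
    cfg <- dish_config(n_explants = 6, coorientation_kappa = 0,
                       explant = explant_params(core_radius = 12,
                                                base_neurite_length = 34,
                                                neurite_count = 90,
                                                club_ending_radius = 1.5),
                       rng_seed = 400 + s)
    r <- run_pipeline(cfg, rng_seed = s)
    if (!is.null(r$rayleigh) && nrow(r$rayleigh) == 1)
      rej <- rej + (r$rayleigh$p_value[1] < 0.05)
  }
  expect_lte(rej / n_dish, 0.2)
})

test_that("plot builders return ggplot objects", {
  m <- data.frame(explant_id = 1:6, asymmetry_pct = c(12, 33, 35, 28, 40, 22),
                  long_orientation_deg = seq(10, 60, by = 10),
                  halo_area = rnorm(6, 4e4, 100), core_area = rnorm(6, 2e3, 10),
                  low_confidence = FALSE, excluded = FALSE, reason = NA)
  s <- summarize_cohort(m)
  expect_s3_class(plot_asymmetry_histogram(s), "ggplot")
  expect_s3_class(plot_orientation_polar(m$long_orientation_deg), "ggplot")
})
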