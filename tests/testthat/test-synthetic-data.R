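# Small, fast explant template used for dish-level simulations in the suite.
tiny_explant <- function(...) {
  explant_params(core_radius = 12, base_neurite_length = 34,
                 neurite_count = 90, club_ending_radius = 1.5, ...)
}

test_that("parameter validation enforces the halo-surrounds-core invariant", {
  expect_error(explant_params(asymmetry_amplitude = 1), "\\[0, 1\\)")
  expect_error(explant_params(asymmetry_amplitude = 1.3), "\\[0, 1\\)")
  expect_error(explant_params(neurite_count = 4), ">= 8")
  expect_error(render_explant(explant_params(), image_size = 64),
               "too small")
})

test_that("rendering is bit-deterministic under a fixed seed", {
  p <- explant_params(asymmetry_amplitude = 0.3, orientation_deg = 123)
  a <- render_explant(p, rng_seed = 99)
  b <- render_explant(p, rng_seed = 99)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$ground_truth, b$ground_truth)

  cfg <- dish_config(n_explants = 3, explant = tiny_explant(), rng_seed = 17)
  d1 <- render_dish(cfg); d2 <- render_dish(cfg)
  expect_identical(d1$image$pixels, d2$image$pixels)
  expect_identical(d1$ground_truth, d2$ground_truth)
})

test_that("measured asymmetry is nondecreasing in the amplitude", {
  amps <- seq(0, 0.6, by = 0.1)
  got <- vapply(amps, function(a) {
    ex <- render_explant(explant_params(asymmetry_amplitude = a),
                         rng_seed = 21, noise_sd = 0)
    measure_dish(segment_explants(ex$image))$asymmetry_pct[1]
  }, 1.0)
  expect_true(all(diff(got) > 0))
  expect_lt(got[1], 3)  # symmetric render measures near 0
})

test_that("per-explant orientations follow the dish co-orientation model", {
  # high concentration: true orientations tightly spread
  d <- render_dish(dish_config(n_explants = 8, coorientation_kappa = 50,
                               explant = tiny_explant(), rng_seed = 31))
  expect_lt(circ_sd_deg(d$ground_truth$orientation_deg), 15)

  # kappa = 0: orientations uniform; Rayleigh on the true orientations of
  # many dishes should be non-significant at close to the nominal rate
  nonsig <- 0; n_dish <- 60
  for (s in seq_len(n_dish)) {
    dd <- render_dish(dish_config(n_explants = 6, coorientation_kappa = 0,
                                  explant = tiny_explant(), rng_seed = 1000 + s))
    p <- suppressWarnings(rayleigh_test(dd$ground_truth$orientation_deg))$p_value
    nonsig <- nonsig + (p > 0.05)
  }
  expect_gte(nonsig / n_dish, 0.9)
})

test_that("dish means are drawn independently per dish", {
  means <- vapply(1:40, function(s) {
    d <- render_dish(dish_config(n_explants = 1, explant = tiny_explant(),
                                 rng_seed = 5000 + s))
    d$ground_truth$dish_mean_orientation_deg[1]
  }, 1.0)
  expect_gt(rayleigh_test(means)$p_value, 0.05)
})

test_that("ground truth flags edge and overlap geometry", {
  # forcing a small separation makes the two halos overlap: flagged merged
  p <- tiny_explant()
  rmax <- halometry:::halo_max_radius(p)
  cfg <- dish_config(n_explants = 2, explant = p, rng_seed = 3,
                     min_separation = rmax,
                     dish_radius = ceiling(1.7 * rmax) + 50)
  d <- render_dish(cfg)
  expect_true(all(d$ground_truth$merged_with_neighbor))

  # a dish barely larger than the halo puts the explant near the edge
  p1 <- tiny_explant()
  rmax <- halometry:::halo_max_radius(p1)
  cfg2 <- dish_config(n_explants = 1, explant = p1, rng_seed = 3,
                      dish_radius = ceiling(rmax + 25), edge_margin = 40)
  expect_error(render_dish(cfg2), "layout error")
})

test_that("scenario renders differ in spectral organization", {
  d <- render_dish(dish_config(scenario = "dissociated", n_explants = 1,
                               dish_radius = 220, rng_seed = 8))
  crop <- field_crops(d$image, data.frame(x = 220 - 64, y = 220 - 64,
                                          size = 128))[[1]]
  thr <- anisotropy_threshold(n = 60, q = 0.99, null = "dissociated",
                              rng_seed = 12)
  expect_lt(spectral_orientation(crop)$anisotropy_score, thr)

  # a halo flank shows organized radial growth
  ex <- render_explant(explant_params(asymmetry_amplitude = 0.35,
                                      orientation_deg = 0), rng_seed = 8)
  c0 <- (nrow(ex$image$pixels) - 1) / 2
  halo_crop <- field_crops(ex$image,
                           data.frame(x = round(c0 + 40),
                                      y = round(c0 - 64), size = 128))[[1]]
  expect_gt(spectral_orientation(halo_crop)$anisotropy_score, thr)
})

test_that("reaggregated clusters measure like explants", {
  d <- render_dish(dish_config(scenario = "reaggregated", n_explants = 3,
                               coorientation_kappa = 30,
                               explant = tiny_explant(), rng_seed = 14))
  m <- measure_dish(segment_explants(d$image))
  ok <- m[!m$excluded, ]
  expect_gte(nrow(ok), 2)
  expect_true(all(ok$asymmetry_pct > 10))
})

test_that("write_dish round-trips image and ground truth", {
  td <- withr::local_tempdir()
  ex <- render_explant(tiny_explant(), rng_seed = 5)
  paths <- write_dish(ex, td, name = "one")
  expect_true(all(file.exists(paths)))
  back <- read_image_field(paths[["image"]])
  expect_equal(dim(back$pixels), dim(ex$image$pixels))
  # 16-bit quantization: intensities round-trip to ~1/65535
  expect_lt(max(abs(back$pixels - ex$image$pixels)), 1e-4)
  gt <- read.csv(paths[["ground_truth"]])
  expect_equal(gt$orientation_deg, ex$ground_truth$orientation_deg)
})
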