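test_that("circular averaging of observer angles", {
  expect_equal(as.numeric(average_observers(c(10, 20))), 15)
  # wraparound: the arithmetic mean would give 180
  expect_equal(as.numeric(average_observers(c(350, 10))) %% 360, 0,
               tolerance = 1e-9)
  expect_warning(amb <- average_observers(c(0, 180)), "zero resultant")
  expect_true(is.na(amb))
  expect_true(attr(amb, "ambiguous"))
})

test_that("decoding inverts the applied rotation", {
  expect_equal(decode_orientation(162, 72), 90)
  expect_equal(decode_orientation(30, 100), 290)
  expect_equal(decode_orientation(45, 0), 45)
})

test_that("blind rotation errors when the crop leaves the image", {
  ex <- render_explant(explant_params(), rng_seed = 1)
  expect_error(blind_rotate(ex$image, radius = 1000), "exceeds image bounds")
})

test_that("rotate-measure-decode round-trips across the rotation grid", {
  ex <- render_explant(explant_params(asymmetry_amplitude = 0.35,
                                      orientation_deg = 30),
                       rng_seed = 13, noise_sd = 0)
  measure_rotated <- function(rot) {
    br <- blind_rotate(ex$image, angle_deg = rot)
    seg <- segment_explants(br$image)
    p <- seg$pairs[[1]]
    as.numeric(morphology_orientation(br$image, p$halo, p$core))
  }
  # the surrogate has a few degrees of measurement error of its own; the
  # ROUND-TRIP property is that decoded orientations agree across rotations
  decoded <- vapply(seq(0, 345, by = 15),
                    function(r) decode_orientation(measure_rotated(r), r), 1.0)
  expect_lt(circ_sd_deg(decoded), 2)
  expect_lt(abs(halometry:::ang_diff(mean_decoded <-
    as.numeric(average_observers(decoded)), 30)), 6)
})

test_that("morphology orientation finds the sparse long side", {
  ex <- render_explant(explant_params(asymmetry_amplitude = 0.35,
                                      orientation_deg = 90,
                                      density_contrast = 0.5),
                       rng_seed = 3, noise_sd = 0)
  seg <- segment_explants(ex$image)
  mo <- morphology_orientation(ex$image, seg$pairs[[1]]$halo,
                               seg$pairs[[1]]$core)
  expect_lt(abs(halometry:::ang_diff(as.numeric(mo), 90)), 10)

  # radially symmetric halo: no-orientation sentinel
  exs <- render_explant(explant_params(asymmetry_amplitude = 0,
                                       density_contrast = 0,
                                       club_ending_radius = 0),
                        rng_seed = 3, noise_sd = 0)
  segs <- segment_explants(exs$image)
  mos <- morphology_orientation(exs$image, segs$pairs[[1]]$halo,
                                segs$pairs[[1]]$core)
  expect_true(is.na(mos))
})

test_that("morphology- and length-based orientations agree across a cohort", {
  set.seed(41)
  oris <- runif(12, 0, 360)
  morph <- len <- numeric(12)
  for (i in seq_along(oris)) {
    ex <- render_explant(explant_params(asymmetry_amplitude = 0.35,
                                        orientation_deg = oris[i]),
                         rng_seed = 600 + i, noise_sd = 0)
    seg <- segment_explants(ex$image)
    len[i] <- measure_dish(seg)$long_orientation_deg[1]
    morph[i] <- as.numeric(morphology_orientation(
      ex$image, seg$pairs[[1]]$halo, seg$pairs[[1]]$core))
  }
  expect_gt(circ_corr(morph, len), 0.8)
  expect_lt(max(abs(halometry:::ang_diff(morph, len))), 20)
})

test_that("simulated observers behave like their von Mises model", {
  # perfect observer
  expect_equal(simulated_observer(123, Inf), 123)

  # uninformative observers: decoded dish means are uniform, so the Rayleigh
  # test rejects only at ~ the nominal rate
  set.seed(19)
  nonsig <- 0; n_dish <- 100
  for (d in seq_len(n_dish)) {
    means <- vapply(1:6, function(i) {
      rot <- runif(1, 0, 360)
      obs <- simulated_observer((45 + rot) %% 360, 0, n = 2)
      as.numeric(average_observers(decode_orientation(obs, rot)))
    }, 1.0)
    nonsig <- nonsig + (rayleigh_test(means)$p_value > 0.05)
  }
  expect_gte(nonsig / n_dish, 0.9)

  # averaging two observers halves the circular variance of the estimate
  set.seed(23)
  reps <- 3000
  one <- rvonmises(reps, 0, 20)
  two <- vapply(seq_len(reps), function(i)
    as.numeric(average_observers(rvonmises(2, 0, 20))), 1.0)
  v1 <- 1 - circ_resultant(one)$r
  v2 <- 1 - circ_resultant(two)$r
  expect_equal(v2 / v1, 0.5, tolerance = 0.12)
})

test_that("the dish-level protocol assigns each explant its own rotation", {
  cfg <- dish_config(n_explants = 5, coorientation_kappa = 50,
                     explant = explant_params(core_radius = 16,
                                              base_neurite_length = 48,
                                              neurite_count = 130,
                                              club_ending_radius = 1.5),
                     rng_seed = 27)
  d <- render_dish(cfg)
  seg <- segment_explants(d$image)
  rec <- orient_explants(d, seg, n_observers = 2, observer_kappa = 50,
                         rng_seed = 8)
  expect_equal(nrow(rec), 5)
  expect_equal(length(unique(round(rec$applied_rotation_deg, 4))), 5)
  # decoded means recover the co-orientation of the dish
  err <- halometry:::axial_diff(rec$mean_orientation_deg,
                                d$ground_truth$dish_mean_orientation_deg[1])
  expect_lt(stats::median(err), 20)
  expect_lt(rayleigh_test(rec$mean_orientation_deg)$p_value, 0.05)
})
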