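test_that("moment ellipse fit recovers circles and axis-aligned ellipses", {
  f <- fit_ellipse(circle_contour(50, center = c(100, 100)))
  expect_equal(f$semi_major, 50, tolerance = 0.5)
  expect_equal(f$semi_minor, 50, tolerance = 0.5)
  expect_equal(unname(f$center), c(100, 100), tolerance = 1e-6)

  g <- fit_ellipse(ellipse_contour(100, 50, 0, center = c(0, 0)))
  expect_equal(g$semi_major, 100, tolerance = 1)   # within 1%
  expect_equal(g$semi_minor, 50, tolerance = 0.5)
  expect_equal(g$major_axis_angle_deg, 0, tolerance = 0.5)
})

test_that("moment fit agrees with the direct least-squares conic fit", {
  for (ang in c(30, 75, 120, 169)) {
    v <- ellipse_contour(100, 50, ang, center = c(30, -20))
    mf <- fit_ellipse(v)
    cf <- conic_ellipse_fit(v)
    expect_equal(mf$major_axis_angle_deg, ang %% 180, tolerance = 0.5)
    expect_equal(mf$major_axis_angle_deg, cf$angle_deg, tolerance = 0.5)
    expect_lt(abs(mf$semi_major - cf$semi_major) / cf$semi_major, 0.01)
    expect_lt(abs(mf$semi_minor - cf$semi_minor) / cf$semi_minor, 0.01)
    expect_equal(unname(mf$center), unname(cf$center), tolerance = 0.1)
  }
})

test_that("degenerate contours are rejected", {
  expect_error(fit_ellipse(cbind(c(0, 1), c(0, 1))), "3 vertices")
  expect_error(fit_ellipse(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
  expect_error(contour_area(cbind(0:1, 0:1)), "degenerate")
})

test_that("asymmetry index reproduces its defining boundary cases", {
  halo <- fit_ellipse(ellipse_contour(200, 120, 0, center = c(300, 300)))
  conc <- fit_ellipse(circle_contour(40, center = c(300, 300)))
  expect_equal(asymmetry_index(halo, conc)$asymmetry_pct, 0, tolerance = 1e-6)

  # core at an end of the major axis: maximal asymmetry
  at_end <- fit_ellipse(circle_contour(
    40, center = c(300 + halo$semi_major, 300)))
  expect_equal(asymmetry_index(halo, at_end)$asymmetry_pct, 100,
               tolerance = 1e-6)

  # halfway: linear in the displacement
  half <- fit_ellipse(circle_contour(
    40, center = c(300 + halo$semi_major / 2, 300)))
  m <- asymmetry_index(halo, half)
  expect_equal(m$asymmetry_pct, 50, tolerance = 1e-6)
  # core toward +x means long neurites point toward 180
  expect_equal(m$long_orientation_deg, 180, tolerance = 1e-6)

  # displacement purely along the MINOR axis projects to zero
  minor <- fit_ellipse(circle_contour(40, center = c(300, 300 - 60)))
  expect_equal(asymmetry_index(halo, minor)$asymmetry_pct, 0,
               tolerance = 1e-6)

  # beyond the major axis end is an error
  beyond <- fit_ellipse(circle_contour(10, center = c(520, 300)))
  expect_error(asymmetry_index(halo, beyond), "beyond")
})

test_that("asymmetry is invariant to rigid motions and scaling", {
  base_halo <- ellipse_contour(150, 90, 20, center = c(0, 0))
  base_core <- circle_contour(30, center = c(48 * cos(20 * pi / 180),
                                             -48 * sin(20 * pi / 180)))
  m0 <- asymmetry_index(fit_ellipse(base_halo), fit_ellipse(base_core))
  for (rot in c(33, 140, 285)) {
    # geometry CCW rotation expressed on raster (y-down) coordinates
    phi <- rot * pi / 180
    R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2, 2)
    h <- sweep(t(R %*% t(base_halo)), 2, c(500, 400), "+")
    k <- sweep(t(R %*% t(base_core)), 2, c(500, 400), "+")
    m <- asymmetry_index(fit_ellipse(h), fit_ellipse(k))
    expect_lt(abs(m$asymmetry_pct - m0$asymmetry_pct), 0.5)
    expect_lt(min(abs(((m$long_orientation_deg - m0$long_orientation_deg) -
                        rot) %% 360), abs((((m$long_orientation_deg -
                        m0$long_orientation_deg) - rot) %% 360) - 360)), 1)
  }
  for (s in c(0.25, 3)) {
    ms <- asymmetry_index(fit_ellipse(base_halo * s),
                          fit_ellipse(base_core * s))
    expect_lt(abs(ms$asymmetry_pct - m0$asymmetry_pct), 0.5)
  }
})

test_that("index stays in range and near-circular halos are flagged", {
  set.seed(8)
  for (i in 1:20) {
    a <- runif(1, 80, 200); b <- runif(1, 0.5, 1) * a
    ang <- runif(1, 0, 180)
    d <- runif(1, 0, 0.95) * a
    phi <- ang * pi / 180
    halo <- fit_ellipse(ellipse_contour(a, b, ang, center = c(0, 0)))
    core <- fit_ellipse(circle_contour(
      10, center = c(d * cos(phi), -d * sin(phi))))
    m <- asymmetry_index(halo, core)
    expect_gte(m$asymmetry_pct, 0)
    expect_lte(m$asymmetry_pct, 100)
  }
  round_halo <- fit_ellipse(ellipse_contour(100, 99.5, 0))
  core <- fit_ellipse(circle_contour(10, center = c(20, 0)))
  expect_true(asymmetry_index(round_halo, core)$low_confidence)
})

test_that("measure_dish carries exclusions and measures the rest", {
  ex <- render_explant(explant_params(asymmetry_amplitude = 0.35),
                       rng_seed = 2, noise_sd = 0)
  seg <- segment_explants(ex$image)
  m <- measure_dish(seg)
  expect_s3_class(m, "dish_measurements")
  expect_equal(nrow(m), 1)
  expect_false(m$excluded[1])

  # force an exclusion flag and check it is carried, not measured
  seg$pairs[[1]]$flags$touches_dish_edge <- TRUE
  seg$pairs[[1]]$flags$excluded <- TRUE
  m2 <- measure_dish(seg)
  expect_true(m2$excluded[1])
  expect_equal(m2$reason[1], "touches_dish_edge")
  expect_true(is.na(m2$asymmetry_pct[1]))

  empty <- structure(list(pairs = list(),
                          flags = halometry:::empty_flags_table()),
                     class = "segmentation_result")
  expect_equal(nrow(measure_dish(empty)), 0)
})
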