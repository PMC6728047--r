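# Independent oracles used across the suite.  Each is deliberately written
# along a different route than the package code it checks.

# Closed ellipse contour in raster coordinates (y down), sampled at n points.
# a, b are semi-axes, angle_deg the major-axis direction in the geometry
# convention (CCW, y up), center in raster coordinates.
ellipse_contour <- function(a, b, angle_deg = 0, center = c(0, 0), n = 720) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  phi <- angle_deg * pi / 180
  gx <- a * cos(th) * cos(phi) - b * sin(th) * sin(phi)
  gy <- a * cos(th) * sin(phi) + b * sin(th) * cos(phi)
  cbind(center[1] + gx, center[2] - gy)  # flip y into raster space
}

circle_contour <- function(r, center = c(0, 0), n = 720) {
  ellipse_contour(r, r, 0, center, n)
}

# Direct least-squares conic (Fitzgibbon) ellipse fit on a vertex set --
# independent of the package's moment-based route.  Returns center (raster),
# semi-axes and major-axis angle in the geometry convention.
conic_ellipse_fit <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  cond <- 4 * Re(eg$vectors[1, ]) * Re(eg$vectors[3, ]) -
    Re(eg$vectors[2, ])^2
  a1 <- Re(eg$vectors[, which(cond > 0)[1]])
  coef <- c(a1, T %*% a1)  # A B C D E F for Ax^2+Bxy+Cy^2+Dx+Ey+F
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; F <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  s <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * (A + C + s)) / den
  ax2 <- -sqrt(num * (A + C - s)) / den
  semi_major <- max(ax1, ax2); semi_minor <- min(ax1, ax2)
  ang_raster <- if (abs(B) < 1e-12 && A <= C) 0
    else if (abs(B) < 1e-12) 90
    else atan2(C - A - s, B) * 180 / pi
  if (ax1 < ax2) ang_raster <- ang_raster + 90
  list(center = c(cx, cy), semi_major = semi_major, semi_minor = semi_minor,
       angle_deg = (-ang_raster) %% 180)  # raster -> geometry flip
}

# Pixel-count area oracle: rasterize the polygon on a unit grid by
# point-in-polygon tests of pixel centers (independent of the shoelace sum).
pixel_count_area <- function(v) {
  xr <- floor(min(v[, 1])):ceiling(max(v[, 1]))
  yr <- floor(min(v[, 2])):ceiling(max(v[, 2]))
  g <- expand.grid(x = xr, y = yr)
  sum(halometry:::point_in_polygon(g$x, g$y, v))
}

# Analytic ground-truth measurement for a rendered explant: evaluates the
# ellipse-fit / asymmetry-index definitions on the exact halo boundary
# (offset ellipse) and core disk by polar-moment integration, without any
# rendering or segmentation.  Returns the expected index (%) and the
# long-neurite orientation (deg).
halo_oracle <- function(core_radius, base_neurite_length, amplitude,
                        orientation_deg, n_grid = 8192) {
  alpha <- core_radius + base_neurite_length
  beta <- alpha * (1 - 0.45 * amplitude)
  delta <- amplitude * alpha
  th <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  ct <- cos(th); st <- sin(th)
  A <- ct^2 / alpha^2 + st^2 / beta^2
  B <- -2 * ct * delta / alpha^2
  C <- delta^2 / alpha^2 - 1
  r <- (-B + sqrt(pmax(B^2 - 4 * A * C, 0))) / (2 * A)
  dth <- 2 * pi / n_grid
  area <- sum(r^2 / 2) * dth
  xbar <- sum(r^3 / 3 * ct) * dth / area   # core center at the origin
  sxx <- sum(r^4 / 4 * ct^2) * dth / area - xbar^2
  syy <- sum(r^4 / 4 * st^2) * dth / area
  # by symmetry sxy = 0 about the orientation axis: axes are (x, y)
  semi_major <- 2 * sqrt(max(sxx, syy))
  semi_minor <- 2 * sqrt(min(sxx, syy))
  sc <- sqrt(area / (pi * semi_major * semi_minor))
  semi_major <- semi_major * sc
  idx <- 100 * abs(xbar) / semi_major
  long_dir <- if (sxx >= syy) orientation_deg %% 360 else NA  # axis flip guard
  list(asymmetry_pct = idx, long_orientation_deg = long_dir,
       semi_major = semi_major, semi_minor = semi_minor,
       halo_center_offset = xbar)
}

# Monte-Carlo Rayleigh p-value: fraction of uniform-null samples of size n
# whose mean resultant length reaches r_obs.  Chunked to bound memory.
mc_rayleigh_p <- function(n, r_obs, nsim, chunk = 1e5) {
  hits <- 0; done <- 0
  while (done < nsim) {
    m <- min(chunk, nsim - done)
    th <- matrix(runif(m * n, 0, 2 * pi), m, n)
    r <- sqrt(rowSums(cos(th))^2 + rowSums(sin(th))^2) / n
    hits <- hits + sum(r >= r_obs)
    done <- done + m
  }
  (hits + 1) / (nsim + 1)
}

# Circular spread (angular deviation, degrees) of a set of angles.
circ_sd_deg <- function(angles_deg) {
  r <- circ_resultant(angles_deg)$r
  sqrt(-2 * log(max(r, 1e-12))) * 180 / pi
}
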