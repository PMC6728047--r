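#' Mean resultant vector of a set of directions
#'
#' Computes the mean resultant length \eqn{r} and mean direction of a set of
#' angles, the basic summary of directional data: each angle is mapped to a
#' unit vector, the vectors are averaged, and \eqn{r} is the length of the
#' average (\eqn{r = 1} iff all angles coincide, \eqn{r = 0} for perfectly
#' balanced angles).
#'
#' @param angles_deg numeric vector of directions in degrees.
#' @return list with components `r` (mean resultant length in \[0, 1\]) and
#'   `mean_deg` (mean direction in \[0, 360); `NA` when `r` is numerically 0).
#' @examples
#' circ_resultant(c(350, 10))   # r close to 1, mean 0
#' circ_resultant(c(0, 90, 180, 270))  # r = 0
#' @export
circ_resultant <- function(angles_deg) {
  if (length(angles_deg) < 1L) stop("need at least one angle")
  if (anyNA(angles_deg)) stop("angles contain NA")
  th <- deg2rad(angles_deg)
  C <- mean(cos(th)); S <- mean(sin(th))
  r <- sqrt(C^2 + S^2)
  mean_deg <- if (r < 1e-12) NA_real_ else wrap360(rad2deg(atan2(S, C)))
  list(r = min(r, 1), mean_deg = mean_deg)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that directions are uniformly distributed on the
#' circle against a unimodal alternative, using the mean resultant length
#' \eqn{r}.  The statistic is \eqn{Z = n r^2} and the p-value uses the
#' standard small-sample series approximation
#' \deqn{p = e^{-Z}\left[1 + \frac{2Z - Z^2}{4n}
#'   - \frac{24Z - 132Z^2 + 76Z^3 - 9Z^4}{288 n^2}\right],}
#' clamped into (0, 1].  The series degrades for extreme concentration
#' (\eqn{Z} close to \eqn{n}), where it can undershoot 0 before clamping; the
#' clamp keeps the decision conservative in the only direction that matters
#' there (p tiny).
#'
#' @param angles_deg numeric vector of directions in degrees.
#' @param axial if `TRUE`, treat the data as axes (mod 180): angles are
#'   doubled before the test and the mean direction halved afterwards.
#' @return object of class `rayleigh_test`: a list with `n`,
#'   `mean_direction_deg`, `r`, `statistic` (Z) and `p_value`.  When `n < 3`
#'   the p-value is of little meaning and the result carries `small_n = TRUE`.
#' @examples
#' rayleigh_test(c(12, 20, 15, 18, 9, 14))
#' @export
rayleigh_test <- function(angles_deg, axial = FALSE) {
  if (length(angles_deg) < 1L) stop("need at least one angle")
  work <- if (axial) wrap360(2 * angles_deg) else angles_deg
  n <- length(work)
  res <- circ_resultant(work)
  r <- res$r
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, .Machine$double.eps), 1)
  mean_dir <- res$mean_deg
  if (axial && !is.na(mean_dir)) mean_dir <- wrap180(mean_dir / 2)
  small_n <- n < 3L
  if (small_n) warning("fewer than 3 angles: Rayleigh p-value is unreliable")
  structure(
    list(n = n, mean_direction_deg = mean_dir, r = r, statistic = Z,
         p_value = p, axial = axial, small_n = small_n),
    class = "rayleigh_test"
  )
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat("Rayleigh test of circular uniformity",
      if (x$axial) "(axial data, angles doubled)" else "", "\n")
  cat(sprintf("  n = %d, r = %.4f, Z = %.4f, p = %.4g\n",
              x$n, x$r, x$statistic, x$p_value))
  if (!is.na(x$mean_direction_deg))
    cat(sprintf("  mean direction = %.2f deg\n", x$mean_direction_deg))
  if (isTRUE(x$small_n)) cat("  warning: n < 3, p-value unreliable\n")
  invisible(x)
}

#' @noRd
#' Ratio A(kappa) = I1(kappa) / I0(kappa) of modified Bessel functions,
#' computed with exponential scaling so large kappa does not overflow.
bessel_ratio <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Draw from the von Mises circular distribution
#'
#' Samples directions from the von Mises distribution with mean direction
#' `mu_deg` and concentration `kappa`, using Best-Fisher rejection sampling
#' from a wrapped Cauchy envelope.  `kappa = 0` reduces exactly to the uniform
#' distribution on \[0, 360).  Uses R's global RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration parameter, \eqn{\ge 0} (`Inf` returns `mu_deg`
#'   exactly).
#' @return numeric vector of `n` angles in \[0, 360).
#' @examples
#' set.seed(1)
#' rvonmises(5, 90, 20)
#' @export
rvonmises <- function(n, mu_deg, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap360(mu_deg), n))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  mu <- deg2rad(mu_deg)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  rho <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rho * z) / (rho + z)
    cc <- kappa * (rho - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(keep)) {
      th <- sign(u3[keep] - 0.5) * acos(f[keep])
      take <- min(sum(keep), n - got)
      out[(got + 1L):(got + take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  wrap360(rad2deg(out + mu))
}

#' Estimate the von Mises concentration parameter
#'
#' Maximum-likelihood estimation of the concentration \eqn{\kappa} from a
#' sample of directions: the sample mean resultant length \eqn{r} is equated
#' to \eqn{A(\kappa) = I_1(\kappa)/I_0(\kappa)} and the equation inverted
#' numerically by bisection.  For very small \eqn{r} (below `1e-8`) the
#' estimate is truncated to 0, since \eqn{A(\kappa) \approx \kappa/2} there
#' and the inversion is dominated by noise.
#'
#' @param angles_deg numeric vector of at least two directions in degrees.
#' @return estimated kappa (`Inf` when all angles coincide, i.e. r = 1).
#' @export
vonmises_kappa <- function(angles_deg) {
  if (length(angles_deg) < 2L) stop("need at least two angles")
  r <- circ_resultant(angles_deg)$r
  if (r >= 1 - 1e-12) return(Inf)
  if (r < 1e-8) return(0)
  # A(kappa) is strictly increasing; bracket then bisect.
  hi <- 2
  while (bessel_ratio(hi) < r && hi < 1e8) hi <- hi * 2
  stats::uniroot(function(k) bessel_ratio(k) - r, c(0, hi),
                 tol = 1e-10)$root
}

#' Fisher-Lee circular correlation coefficient
#'
#' Correlation between two paired samples of directions, invariant to
#' rotations of either sample.  Values near 1 indicate that the two angle
#' sets co-rotate.
#'
#' @param a_deg,b_deg paired angle vectors in degrees, equal length >= 2.
#' @return correlation coefficient in \[-1, 1\].
#' @export
circ_corr <- function(a_deg, b_deg) {
  stopifnot(length(a_deg) == length(b_deg), length(a_deg) >= 2)
  a <- deg2rad(a_deg); b <- deg2rad(b_deg)
  n <- length(a)
  num <- 0; d1 <- 0; d2 <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    num <- num + sum(sin(a[i] - a[j]) * sin(b[i] - b[j]))
    d1 <- d1 + sum(sin(a[i] - a[j])^2)
    d2 <- d2 + sum(sin(b[i] - b[j])^2)
  }
  if (d1 == 0 || d2 == 0) return(NA_real_)
  num / sqrt(d1 * d2)
}
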