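#' Von Mises sampling and density (degree scale)
#'
#' Minimal circular-distribution primitives used by the report simulator
#' and the mixture model. Angles are in degrees; `mu` is the mean
#' direction and `kappa >= 0` the concentration (kappa = 0 is the circular
#' uniform).
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter (>= 0).
#' @return `rvonmises`: draws in degrees in \[0, 360);
#'   `dvonmises_deg`: density per degree.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(stats::runif(n, 0, 360))
  # Best & Fisher (1979) rejection sampler, radians internally
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f)
      out[i] <- theta
      i <- i + 1L
    }
  }
  wrap360(mu + rad2deg(out))
}

#' @rdname rvonmises
#' @param x angles in degrees at which to evaluate the density.
#' @export
dvonmises_deg <- function(x, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(rep(1 / 360, length(x)))
  d <- deg2rad(signed_circular_diff(mu, x))
  # log I0(kappa) computed from the exponentially scaled Bessel function
  # so large concentrations do not overflow
  log_i0 <- log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
  exp(kappa * cos(d) - log(2 * pi) - log_i0) * pi / 180
}
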