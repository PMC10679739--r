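#' Circular utilities and feature-continuous accuracy
#'
#' Directions are handled in degrees on \[0, 360), with 0 degrees pointing
#' up and angles increasing clockwise. Radians are used internally where a
#' kernel or density needs them.
#'
#' @name angles
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into \[0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into \[0, 360).
#' @export
wrap360 <- function(x) {
  out <- x %% 360
  # -1e-15 %% 360 can return 360 exactly due to floating point
  out[out >= 360] <- 0
  out
}

#' Signed circular difference
#'
#' Shortest signed arc from `from` to `to`, in degrees in (-180, 180].
#'
#' @param from,to numeric vectors of angles in degrees.
#' @return signed difference `to - from` wrapped into (-180, 180].
#' @export
signed_circular_diff <- function(from, to) {
  d <- (to - from) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Absolute circular deviation between two directions
#'
#' Shortest-arc distance on the circle between a stimulus (or true)
#' direction and a reported (or reconstructed) direction, in degrees in
#' \[0, 180\]. This is the trial-wise error measure from which the
#' feature-continuous accuracy is computed.
#'
#' @param theta_s,theta_r numeric vectors of directions in degrees.
#' @return absolute deviations in degrees, in \[0, 180\].
#' @export
#' @examples
#' circular_deviation(10, 350)  # 20
#' circular_deviation(0, 180)   # 180
circular_deviation <- function(theta_s, theta_r) {
  stopifnot(is.numeric(theta_s), is.numeric(theta_r),
            all(is.finite(theta_s)), all(is.finite(theta_r)))
  abs(signed_circular_diff(theta_s, theta_r))
}

#' Feature-continuous accuracy (FCA)
#'
#' Rescales an absolute circular deviation into a percentage accuracy:
#' 0 degrees of error maps to 100, 90 degrees (chance for uniform
#' guessing) to 50, and 180 degrees to 0.
#'
#' @param deviation numeric vector of absolute deviations in degrees,
#'   each in \[0, 180\].
#' @return FCA values in percent, in \[0, 100\].
#' @export
#' @examples
#' fca(c(0, 90, 180))
fca <- function(deviation) {
  if (any(!is.finite(deviation)) || any(deviation < 0) || any(deviation > 180))
    stop("deviations must be finite and lie in [0, 180] degrees")
  (180 - deviation) / 180 * 100
}
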