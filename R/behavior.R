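#' Fit a von Mises mixture model to signed circular report errors
#'
#' Maximum-likelihood fit of a three-component mixture on the circle of
#' signed errors (report minus target, in (-180, 180\]): a target von
#' Mises centered at 0, an opposite-direction von Mises centered at 180
#' degrees (sharing the same concentration), and a circular-uniform
#' guessing component. The opposite weight quantifies the rate of reports
#' of opposite direction (ROOD). Optimization runs in unconstrained space
#' (softmax weights, log concentration) with seeded multi-start.
#'
#' @param errors signed circular errors in degrees (any wrap; reduced to
#'   (-180, 180\] internally). At least 20 values.
#' @param n_restarts number of optimizer restarts.
#' @param seed integer seed for the restart jitter.
#' @return list (class `vmmm_fit`) with `w_detect`, `w_opposite`,
#'   `w_guess`, `kappa`, `loglik`, `n_trials`, `convergence`.
#' @export
fit_vmmm <- function(errors, n_restarts = 10, seed = 1) {
  errors <- errors[is.finite(errors)]
  n <- length(errors)
  if (n < 20) stop("need at least 20 trials to fit the mixture (got ", n, ")")
  x <- signed_circular_diff(0, errors)  # wrap into (-180, 180]

  # parameters: (a_detect, a_opposite, log kappa); weights via softmax
  # with the guess logit fixed at 0
  nll <- function(p) {
    a <- c(p[1], p[2], 0)
    w <- exp(a - max(a)); w <- w / sum(w)
    kappa <- exp(p[3])
    if (!is.finite(kappa) || kappa > 1e6) return(1e10)
    dens <- w[1] * dvonmises_deg(x, 0, kappa) +
            w[2] * dvonmises_deg(x, 180, kappa) +
            w[3] / 360
    -sum(log(pmax(dens, 1e-300)))
  }

  set.seed(as.integer(seed))
  starts <- rbind(
    c(0, -2, log(5)),
    matrix(c(stats::rnorm(2 * (n_restarts - 1), 0, 2),
             stats::rnorm(n_restarts - 1, log(5), 1)),
           ncol = 3)
  )[seq_len(n_restarts), , drop = FALSE]

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("vMMM optimization failed on all ", n_restarts, " restarts")
  a <- c(best$par[1], best$par[2], 0)
  w <- exp(a - max(a)); w <- w / sum(w)
  structure(list(w_detect = w[1], w_opposite = w[2], w_guess = w[3],
                 kappa = exp(best$par[3]), loglik = -best$value,
                 n_trials = n, convergence = best$convergence),
            class = "vmmm_fit")
}

#' @export
print.vmmm_fit <- function(x, ...) {
  cat(sprintf(
    "vMMM fit (n = %d): w_detect = %.3f, w_opposite (ROOD) = %.3f, w_guess = %.3f, kappa = %.2f\n",
    x$n_trials, x$w_detect, x$w_opposite, x$w_guess, x$kappa))
  invisible(x)
}

#' Screen a participant on full-coherence behavior
#'
#' Applies the two pre-scanning exclusion rules on full-coherence trials:
#' the 95th percentile of the absolute circular deviation must not exceed
#' 36.5 degrees (precision rule), and the fitted opposite-report rate
#' (ROOD) must not exceed 5%.
#'
#' @param trials full-coherence trial rows with `theta_s` and `theta_r`.
#' @param p95_cutoff precision cutoff in degrees.
#' @param rood_cutoff maximum tolerated opposite-report mixture weight.
#' @param ... passed to [fit_vmmm()].
#' @return list (class `screening_result`) with `p95_deviation`,
#'   `rood_rate`, `include`, `reasons`, `vmmm`.
#' @export
screen_participant <- function(trials, p95_cutoff = 36.5,
                               rood_cutoff = 0.05, ...) {
  ok <- is.finite(trials$theta_r)
  if (sum(ok) < 20)
    stop("too few reported full-coherence trials to screen (", sum(ok), ")")
  dev <- circular_deviation(trials$theta_s[ok], trials$theta_r[ok])
  p95 <- unname(stats::quantile(dev, 0.95, type = 7))
  vm <- fit_vmmm(signed_circular_diff(trials$theta_s[ok],
                                      trials$theta_r[ok]), ...)
  reasons <- character(0)
  if (p95 > p95_cutoff)
    reasons <- c(reasons, sprintf("p95 deviation %.1f > %.1f deg",
                                  p95, p95_cutoff))
  if (vm$w_opposite > rood_cutoff)
    reasons <- c(reasons, sprintf("ROOD rate %.3f > %.2f",
                                  vm$w_opposite, rood_cutoff))
  structure(list(p95_deviation = p95, rood_rate = vm$w_opposite,
                 include = length(reasons) == 0, reasons = reasons,
                 vmmm = vm),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("screening: p95 = %.1f deg, ROOD = %.3f -> %s\n",
              x$p95_deviation, x$rood_rate,
              if (x$include) "include" else
                paste("exclude:", paste(x$reasons, collapse = "; "))))
  invisible(x)
}
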