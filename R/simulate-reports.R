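#' Default report-mixture parameters per coherence
#'
#' Per-coherence weights of the three-component report model (target von
#' Mises, opposite von Mises at +180 degrees, circular-uniform guessing)
#' and the shared concentration. At zero coherence there is no direction
#' signal, so the generator forces pure guessing. The nonzero-coherence
#' defaults describe an included observer: nearly always detecting at full
#' coherence with tight reports, and a substantial guessing fraction at
#' the intermediate level.
#'
#' @return a `data.frame` with columns `coherence`, `w_detect`,
#'   `w_opposite`, `w_guess`, `kappa`.
#' @export
default_report_mixture <- function() {
  data.frame(
    coherence  = c("zero", "intermediate", "full"),
    w_detect   = c(0.00, 0.65, 0.96),
    w_opposite = c(0.00, 0.03, 0.01),
    w_guess    = c(1.00, 0.32, 0.03),
    kappa      = c(0,    8,    20),
    stringsAsFactors = FALSE
  )
}

#' Simulate continuous direction reports
#'
#' Draws a reported direction for every trial from a von Mises mixture
#' around the trial's stimulus direction: with probability `w_detect` a
#' von Mises draw centered on the target, with `w_opposite` a von Mises
#' draw centered 180 degrees away (an opposite-direction report), and with
#' `w_guess` a uniform guess. At zero coherence the detection and opposite
#' weights are forced to zero (no direction information exists).
#'
#' The function also fills the `theta_gen` column, the direction that
#' drives voxel responses in [simulate_betas()]: the stimulus direction at
#' nonzero coherence and, at zero coherence, a latent direction whose
#' relation to the report is set by `zero_latent`:
#' \describe{
#'   \item{"report"}{the latent equals the guessed report — the guess
#'     reflects the internal direction state that also drives tuned voxels
#'     (default).}
#'   \item{"independent"}{the latent is an independent uniform draw, so
#'     voxel activity carries no information about the report.}
#' }
#'
#' @param trials a trial table from [generate_trial_sequence()].
#' @param mixture a `data.frame` as returned by [default_report_mixture()];
#'   must contain one row per coherence label present in `trials`.
#' @param zero_latent `"report"` or `"independent"`, see Details.
#' @param seed integer seed.
#' @return the trial table with `theta_r` and `theta_gen` filled in.
#' @export
simulate_reports <- function(trials, mixture = default_report_mixture(),
                             zero_latent = c("report", "independent"),
                             seed = 1) {
  zero_latent <- match.arg(zero_latent)
  set.seed(as.integer(seed))
  need <- c("w_detect", "w_opposite", "w_guess", "kappa")
  stopifnot(all(c("coherence", need) %in% names(mixture)))
  if (any(mixture[need] < 0) || any(mixture$kappa < 0))
    stop("mixture weights and kappa must be nonnegative")
  wsum <- rowSums(mixture[c("w_detect", "w_opposite", "w_guess")])
  if (any(abs(wsum - 1) > 1e-8))
    stop("mixture weights must sum to 1 for every coherence level")
  missing_coh <- setdiff(unique(trials$coherence), mixture$coherence)
  if (length(missing_coh))
    stop("no mixture row for coherence level(s): ",
         paste(missing_coh, collapse = ", "))

  n <- nrow(trials)
  theta_r <- numeric(n)
  for (i in seq_len(n)) {
    m <- mixture[mixture$coherence == trials$coherence[i], ]
    w <- c(m$w_detect, m$w_opposite, m$w_guess)
    if (trials$coherence_level[i] == 0) w <- c(0, 0, 1)
    comp <- sample.int(3, 1, prob = w)
    theta_r[i] <- switch(comp,
      rvonmises(1, trials$theta_s[i], m$kappa),
      rvonmises(1, trials$theta_s[i] + 180, m$kappa),
      stats::runif(1, 0, 360))
  }
  trials$theta_r <- theta_r
  is_zero <- trials$coherence_level == 0
  trials$theta_gen <- trials$theta_s
  trials$theta_gen[is_zero] <- if (zero_latent == "report") {
    theta_r[is_zero]
  } else {
    stats::runif(sum(is_zero), 0, 360)
  }
  trials
}
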