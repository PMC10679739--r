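#' Per-run gaze-position noise (standard deviation)
#'
#' Combined spatial SD of the valid gaze samples of each run:
#' `sqrt(var(x) + var(y))`, in dva.
#'
#' @param gaze a `gaze_record`.
#' @return named numeric vector of per-run SDs.
#' @export
gaze_run_sd <- function(gaze) {
  ok <- gaze$valid_sample
  runs <- sort(unique(gaze$run))
  out <- vapply(runs, function(r) {
    g <- gaze[ok & gaze$run == r, ]
    sqrt(stats::var(g$x) + stats::var(g$y))
  }, numeric(1))
  names(out) <- runs
  out
}

#' Run-noise exclusion threshold from a kernel density estimate
#'
#' Estimates the density of run-level gaze-position SDs (pooled over runs
#' and subjects) with a Gaussian kernel and the normal-reference
#' bandwidth, and returns the value at which the estimated CDF reaches
#' `prob`. With `prob = 0.9` this excludes the noisiest ~10% of runs.
#'
#' @param run_sds numeric vector of run SDs (>= 10 values).
#' @param prob CDF probability at which to place the threshold.
#' @return the threshold (clamped to the sample range).
#' @export
run_noise_threshold <- function(run_sds, prob = 0.9) {
  run_sds <- run_sds[is.finite(run_sds)]
  if (length(run_sds) < 10)
    stop("need at least 10 run SDs to estimate a noise threshold")
  if (diff(range(run_sds)) == 0)
    stop("degenerate input: all run SDs are equal")
  d <- stats::density(run_sds, bw = "nrd0")
  cdf <- cumsum(d$y)
  cdf <- cdf / cdf[length(cdf)]
  # first crossing, linearly interpolated on the unique CDF grid
  thr <- stats::approx(cdf, d$x, xout = prob, ties = "ordered")$y
  min(max(thr, min(run_sds)), max(run_sds))
}

#' Reject trials with fixation breaks
#'
#' A trial is rejected when the radial gaze distance from fixation exceeds
#' `threshold` dva continuously for more than `min_duration` s within its
#' 2 s stimulation window. Invalid samples (blinks, missing data) are not
#' interpolated and do not count toward an excursion. Trials without any
#' gaze coverage are flagged unscorable.
#'
#' @param gaze a `gaze_record` aligned to `trials` (shared `trial_id`).
#' @param trials a trial table.
#' @param threshold radial deviation threshold in dva.
#' @param min_duration minimum continuous excursion duration in seconds;
#'   both comparisons are strict.
#' @return list (class `qc_report`) with `rejected` (data.frame of
#'   `trial_id`, `excursion_s`), `unscorable` (trial ids),
#'   `fraction_rejected`, and `valid` (logical per trial, in `trials`
#'   order: TRUE iff scorable and not rejected).
#' @export
reject_trials <- function(gaze, trials, threshold = 2, min_duration = 0.2) {
  rate <- attr(gaze, "sampling_rate")
  if (is.null(rate)) {
    dts <- diff(sort(gaze$time[gaze$trial_id == gaze$trial_id[1]]))
    rate <- 1 / stats::median(dts)
  }
  dt <- 1 / rate
  ids <- trials$trial_id
  exc <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    g <- gaze[gaze$trial_id == ids[i], ]
    if (nrow(g) == 0) next
    r <- sqrt(g$x^2 + g$y^2)
    over <- g$valid_sample & !is.na(r) & r > threshold
    if (!any(over)) { exc[i] <- 0; next }
    runs <- rle(over)
    exc[i] <- max(runs$lengths[runs$values]) * dt
  }
  unscorable <- ids[is.na(exc)]
  rejected_mask <- !is.na(exc) & exc > min_duration
  rejected <- data.frame(trial_id = ids[rejected_mask],
                         excursion_s = exc[rejected_mask])
  valid <- !is.na(exc) & !rejected_mask
  structure(list(rejected = rejected,
                 unscorable = unscorable,
                 fraction_rejected = mean(rejected_mask),
                 valid = valid),
            class = "qc_report")
}

#' Full fixation QC: run screening plus trial rejection
#'
#' Computes per-run gaze SDs, derives the run-noise threshold (from
#' `reference_sds` when supplied — e.g. pooled over subjects — otherwise
#' from this session's runs), excludes runs above it, rejects trials with
#' fixation breaks, and returns the combined validity mask.
#'
#' @param gaze a `gaze_record`.
#' @param trials a trial table.
#' @param reference_sds optional vector of run SDs defining the threshold
#'   distribution (defaults to this session's run SDs).
#' @param ... passed to [reject_trials()].
#' @return list (class `qc_report`) with `run_sd`, `noise_threshold`,
#'   `excluded_runs`, `rejected`, `unscorable`, `fraction_rejected`,
#'   `valid`.
#' @export
apply_fixation_qc <- function(gaze, trials, reference_sds = NULL, ...) {
  run_sd <- gaze_run_sd(gaze)
  ref <- if (is.null(reference_sds)) run_sd else reference_sds
  thr <- run_noise_threshold(ref)
  excluded_runs <- as.integer(names(run_sd))[run_sd > thr]
  rep0 <- reject_trials(gaze, trials, ...)
  valid <- rep0$valid & !(trials$run %in% excluded_runs)
  structure(list(run_sd = run_sd, noise_threshold = thr,
                 excluded_runs = excluded_runs, rejected = rep0$rejected,
                 unscorable = rep0$unscorable,
                 fraction_rejected = mean(!valid), valid = valid),
            class = "qc_report")
}
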