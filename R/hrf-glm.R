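#' Canonical double-gamma hemodynamic response function
#'
#' The standard two-gamma HRF (peak near 5 s, undershoot near 15 s,
#' undershoot ratio 1/6), evaluated at times `t` in seconds.
#'
#' @param t times in seconds (>= 0 contribute; negative times return 0).
#' @return HRF values (unnormalized).
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

# Boxcar-convolved trial regressors sampled at scan times.
# One column per onset: a `duration`-s boxcar at the onset convolved with
# the canonical HRF on a fine grid (dt), then sampled at t = (0:(n-1))*tr.
trial_regressors <- function(onsets, duration, tr, n_scans, dt = 0.1) {
  t_end <- n_scans * tr
  fine <- seq(0, t_end + 32, by = dt)
  hrf <- canonical_hrf(seq(0, 32, by = dt))
  scan_t <- (seq_len(n_scans) - 1) * tr
  X <- vapply(onsets, function(on) {
    box <- as.numeric(fine >= on & fine < on + duration)
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_along(fine)] * dt
    stats::approx(fine, conv, xout = scan_t, rule = 2)$y
  }, numeric(n_scans))
  matrix(X, nrow = n_scans)
}

#' Build a trial-wise GLM design matrix for one run
#'
#' One boxcar-convolved regressor per trial (2 s stimulus period convolved
#' with the canonical HRF), six head-motion nuisance regressors and an
#' intercept.
#'
#' @param trials trial table rows of a single run (must carry `onset`).
#' @param tr repetition time in seconds.
#' @param n_scans number of volumes in the run.
#' @param motion `n_scans` x 6 matrix of motion parameters.
#' @param hrf HRF model id; only `"canonical"` (double gamma) is provided.
#' @param stim_duration stimulus boxcar duration in seconds.
#' @return a list (class `design_matrix`) with `X` (`n_scans` x
#'   (`n_trials` + 7)), `trial_ids`, `labels`, `tr`.
#' @export
build_design_matrix <- function(trials, tr, n_scans, motion,
                                hrf = "canonical", stim_duration = 2) {
  stopifnot(hrf == "canonical", tr > 0)
  if (length(unique(trials$run)) > 1)
    stop("build_design_matrix expects trials from a single run")
  motion <- as.matrix(motion)
  if (nrow(motion) != n_scans || ncol(motion) != 6)
    stop("motion must be an n_scans x 6 matrix")
  if (nrow(trials) > 0 &&
      any(trials$onset + stim_duration > n_scans * tr))
    stop("trial onset beyond run end (",
         round(max(trials$onset), 1), " s vs ", n_scans * tr, " s of scans)")
  Xtr <- trial_regressors(trials$onset, stim_duration, tr, n_scans)
  if (ncol(Xtr) > 0 && any(colSums(abs(Xtr)) == 0))
    stop("a trial regressor is all zero; check onsets and tr")
  X <- cbind(Xtr, motion, 1)
  labels <- c(if (nrow(trials)) paste0("trial_", trials$trial_id),
              paste0("motion_", 1:6), "intercept")
  colnames(X) <- labels
  structure(list(X = X, trial_ids = trials$trial_id, labels = labels,
                 tr = tr),
            class = "design_matrix")
}

#' Estimate trial-wise response amplitudes by ordinary least squares
#'
#' Fits the trial-wise GLM to every voxel's time series jointly
#' (least-squares-all: all trial regressors in one model per run) and
#' returns only the trial coefficients.
#'
#' @param series `n_scans` x `n_voxels` matrix of time-series values.
#' @param design a `design_matrix` from [build_design_matrix()].
#' @return `n_trials` x `n_voxels` matrix of amplitude estimates, with the
#'   trial ids as an attribute `trial_ids`.
#' @export
estimate_trial_betas <- function(series, design) {
  series <- as.matrix(series)
  X <- design$X
  if (nrow(series) != nrow(X))
    stop("series length (", nrow(series), ") does not match design scan count (",
         nrow(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- design$labels[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  coefs <- qr.coef(qrX, series)
  n_trials <- length(design$trial_ids)
  out <- coefs[seq_len(n_trials), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trial_ids") <- design$trial_ids
  out
}

#' Simulate a volumetric BOLD run
#'
#' Generates per-voxel time series for one run: each trial contributes a
#' 2 s boxcar at its onset, scaled by the voxel's trial amplitude from the
#' tuning model (tuning profile at the trial's generative direction plus
#' Gaussian trial noise), convolved with the canonical HRF; an AR(1) scan
#' noise process and six slowly drifting motion nuisance time courses are
#' added on top.
#'
#' @param trials trial table rows of a single run.
#' @param voxels a `voxel_population`.
#' @param tr repetition time in seconds.
#' @param noise_spec list with `scan_sd` (AR(1) innovation SD, default 0),
#'   `ar` (AR(1) coefficient, default 0.3), `trial_noise` (logical: add the
#'   voxel-level Gaussian trial noise to amplitudes, default TRUE),
#'   `motion_sd` (innovation SD of the motion random walks) and
#'   `motion_leak` (coefficient coupling motion into the signal, default 0).
#' @param seed integer seed.
#' @param pad seconds of scanning appended after the last trial ends.
#' @return list with `series` (`n_scans` x `n_voxels`), `motion`
#'   (`n_scans` x 6), `amplitudes` (the generating trial amplitudes),
#'   `tr`, `n_scans`, `trial_ids`.
#' @export
simulate_bold_run <- function(trials, voxels, tr = 0.8,
                              noise_spec = list(), seed = 1, pad = 20) {
  stopifnot(tr > 0)
  spec <- utils::modifyList(list(scan_sd = 0, ar = 0.3, trial_noise = TRUE,
                                 motion_sd = 0.02, motion_leak = 0),
                            noise_spec)
  if (length(unique(trials$run)) > 1)
    stop("simulate_bold_run expects trials from a single run")
  set.seed(as.integer(seed))
  n_scans <- ceiling((max(trials$onset) + 2 + pad) / tr)
  v <- nrow(voxels)
  # trial amplitudes: tuning bump only; the voxel baseline enters the
  # series as a constant offset and is absorbed by the GLM intercept
  amp <- sweep(voxel_tuning(voxels, trials$theta_gen), 2,
               voxels$baseline, "-")
  if (spec$trial_noise && any(voxels$noise_sd > 0)) {
    eps <- matrix(stats::rnorm(length(amp)), nrow(amp), ncol(amp))
    amp <- amp + sweep(eps, 2, voxels$noise_sd, "*")
  }
  Xtr <- trial_regressors(trials$onset, 2, tr, n_scans)
  series <- sweep(Xtr %*% amp, 2, voxels$baseline, "+")
  motion <- apply(matrix(stats::rnorm(n_scans * 6, sd = spec$motion_sd),
                         n_scans, 6), 2, cumsum)
  if (spec$motion_leak != 0)
    series <- series + spec$motion_leak * rowSums(motion)
  if (spec$scan_sd > 0) {
    noise <- vapply(seq_len(v), function(j) {
      as.numeric(stats::filter(stats::rnorm(n_scans, sd = spec$scan_sd),
                               spec$ar, method = "recursive"))
    }, numeric(n_scans))
    series <- series + noise
  }
  list(series = series, motion = motion, amplitudes = amp, tr = tr,
       n_scans = n_scans, trial_ids = trials$trial_id)
}
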