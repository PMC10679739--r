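qc_trials <- function(n_runs = 2, seed = 31) {
  generate_trial_sequence(n_runs, 16, coherence_levels = c(full = 1),
                          seed = seed)
}

test_that("run SDs combine both gaze axes", {
  tt <- qc_trials()
  gz <- simulate_gaze(tt, fixation_sd = 0.2, sampling_rate = 250, seed = 32)
  sds <- gaze_run_sd(gz)
  expect_length(sds, 2)
  # sqrt(var(x) + var(y)) of iid N(0, 0.2) per axis is ~ 0.2 * sqrt(2)
  expect_true(all(abs(sds - 0.2 * sqrt(2)) < 0.03))
})

test_that("the KDE threshold excludes about the noisiest 10% of runs", {
  set.seed(33)
  sds <- rlnorm(2000, log(0.2), 0.4)
  thr <- run_noise_threshold(sds, prob = 0.9)
  frac <- mean(sds > thr)
  expect_lt(abs(frac - 0.1), 0.01)
  # monotone in prob, and clamped to the sample range
  expect_lt(run_noise_threshold(sds, 0.5), thr)
  expect_gte(run_noise_threshold(sds, 0.999999), min(sds))
  expect_lte(run_noise_threshold(sds, 0.999999), max(sds))
  expect_error(run_noise_threshold(sds[1:5]), "at least 10")
  expect_error(run_noise_threshold(rep(0.2, 20)), "degenerate")
})

test_that("trial rejection requires a continuous supra-threshold excursion", {
  tt <- qc_trials()
  id <- tt$trial_id
  exc <- data.frame(
    trial_id = c(id[1], id[2], id[3], id[3]),
    onset = c(0.5, 0.5, 0.3, 1.2),
    duration = c(0.30, 0.15, 0.15, 0.15),
    amplitude = 4)
  gz <- simulate_gaze(tt, fixation_sd = 0.05, excursions = exc,
                      sampling_rate = 1000, seed = 34)
  rep_ <- reject_trials(gz, tt, threshold = 2, min_duration = 0.2)
  # 300 ms excursion: rejected; 150 ms: kept; two disjoint 150 ms: kept
  expect_equal(rep_$rejected$trial_id, id[1])
  expect_gt(rep_$rejected$excursion_s, 0.2)
  expect_true(all(rep_$valid[-1]))
  expect_false(rep_$valid[1])
  expect_equal(rep_$fraction_rejected, 1 / nrow(tt))
})

test_that("blinks interrupt excursions instead of extending them", {
  tt <- qc_trials()
  id <- tt$trial_id
  # 400 ms excursion with a blink cutting it into two 175 ms halves
  exc <- data.frame(trial_id = id[1], onset = 0.5, duration = 0.4,
                    amplitude = 4)
  blink <- data.frame(trial_id = id[1], onset = 0.675, duration = 0.05)
  gz <- simulate_gaze(tt, fixation_sd = 0.05, excursions = exc,
                      blinks = blink, sampling_rate = 1000, seed = 35)
  rep_ <- reject_trials(gz, tt, threshold = 2, min_duration = 0.2)
  expect_true(rep_$valid[1])
  # without the blink the same excursion is rejected
  gz2 <- simulate_gaze(tt, fixation_sd = 0.05, excursions = exc,
                       sampling_rate = 1000, seed = 35)
  expect_false(reject_trials(gz2, tt)$valid[1])
})

test_that("excursions cannot be placed outside the stimulation window", {
  tt <- qc_trials()
  expect_error(
    simulate_gaze(tt, excursions = data.frame(trial_id = tt$trial_id[1],
                                              onset = 1.9, duration = 0.3,
                                              amplitude = 4)),
    "outside the stimulation window")
})

test_that("rejection is monotone in threshold and duration", {
  tt <- qc_trials(n_runs = 4, seed = 36)
  set.seed(37)
  n_exc <- 20
  exc <- data.frame(trial_id = sample(tt$trial_id, n_exc),
                    onset = runif(n_exc, 0, 1),
                    duration = runif(n_exc, 0.05, 0.8),
                    amplitude = runif(n_exc, 1, 5))
  exc <- exc[exc$onset + exc$duration <= 2, ]
  gz <- simulate_gaze(tt, fixation_sd = 0.05, excursions = exc,
                      sampling_rate = 500, seed = 38)
  n_rej <- function(thr, dur)
    nrow(reject_trials(gz, tt, threshold = thr, min_duration = dur)$rejected)
  expect_gte(n_rej(1, 0.2), n_rej(2, 0.2))
  expect_gte(n_rej(2, 0.1), n_rej(2, 0.3))
})

test_that("trials without gaze coverage are unscorable, not rejected", {
  tt <- qc_trials()
  gz <- simulate_gaze(tt, fixation_sd = 0.05, sampling_rate = 250, seed = 39)
  gz_missing <- gz[gz$trial_id != tt$trial_id[5], ]
  attr(gz_missing, "sampling_rate") <- 250
  rep_ <- reject_trials(gz_missing, tt)
  expect_equal(rep_$unscorable, tt$trial_id[5])
  expect_false(rep_$valid[5])
  expect_equal(nrow(rep_$rejected), 0)
})

test_that("full fixation QC combines run and trial exclusion", {
  tt <- qc_trials(n_runs = 3, seed = 40)
  # small enough not to inflate run 1's own SD past the reference threshold
  exc <- data.frame(trial_id = tt$trial_id[1], onset = 0.5, duration = 0.3,
                    amplitude = 3)
  gz <- simulate_gaze(tt, fixation_sd = 0.1, excursions = exc,
                      sampling_rate = 250, seed = 41)
  # inflate run 3's jitter so it crosses the reference threshold
  bump <- gz$run == 3 & gz$valid_sample
  gz$x[bump] <- gz$x[bump] * 6
  ref <- seq(0.1, 0.6, length.out = 20)  # reference distribution of run SDs
  qc <- apply_fixation_qc(gz, tt, reference_sds = ref)
  expect_true(3 %in% qc$excluded_runs)
  expect_true(all(!qc$valid[tt$run == 3]))
  expect_false(qc$valid[1])                    # excursion trial
  expect_true(all(qc$valid[tt$run %in% c(1, 2)][-1]))
  expect_equal(qc$fraction_rejected, mean(!qc$valid))
})

test_that("gaze records round-trip through TSV", {
  tt <- qc_trials()
  blink <- data.frame(trial_id = tt$trial_id[2], onset = 0.2, duration = 0.1)
  gz <- simulate_gaze(tt, blinks = blink, sampling_rate = 100, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_record(gz, path)
  back <- read_gaze_record(path, sampling_rate = 100)
  expect_equal(back$x, gz$x, tolerance = 1e-12)
  expect_equal(back$valid_sample, gz$valid_sample)
  expect_equal(reject_trials(back, tt)$valid, reject_trials(gz, tt)$valid)
})
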