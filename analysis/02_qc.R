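#!/usr/bin/env Rscript
# Stage 2: fixation quality control.
#
# Computes per-run gaze-position SDs, derives the kernel-density run-noise
# threshold (here from the session's own runs plus a reference spread, as
# a stand-in for the multi-subject pool), excludes noisy runs and rejects
# trials with a continuous > 2 dva excursion lasting > 200 ms. The updated
# validity mask is written back into the events table.
#
# Inputs:  results/events.tsv, results/gaze.tsv
# Outputs: results/events.tsv (valid column updated), results/qc_summary.csv

library(gprdecode)

trials <- read_trial_table("results/events.tsv")
gaze <- read_gaze_record("results/gaze.tsv", sampling_rate = 250)

# reference run-SD distribution standing in for the multi-subject pool
reference_sds <- c(gaze_run_sd(gaze), seq(0.1, 0.5, length.out = 10))
qc <- apply_fixation_qc(gaze, trials, reference_sds = reference_sds)

trials$valid <- trials$valid & qc$valid
write_trial_table(trials, "results/events.tsv")

summary_df <- data.frame(
  run = as.integer(names(qc$run_sd)),
  run_sd = as.numeric(qc$run_sd),
  run_excluded = as.integer(names(qc$run_sd)) %in% qc$excluded_runs,
  n_trials_rejected = vapply(as.integer(names(qc$run_sd)), function(r)
    sum(qc$rejected$trial_id %in% trials$trial_id[trials$run == r]),
    integer(1)))
write.csv(summary_df, "results/qc_summary.csv", row.names = FALSE)

cat(sprintf("noise threshold %.3f dva; %d run(s) excluded; %d trial(s) rejected; %.1f%% of trials remain valid\n",
            qc$noise_threshold, length(qc$excluded_runs),
            nrow(qc$rejected), 100 * mean(trials$valid)))
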