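#!/usr/bin/env Rscript
# Stage 1: simulate one subject's session.
#
# Generates the pseudo-randomized trial sequence (10 runs x 48 trials:
# 16 trials each at zero, intermediate and full motion coherence),
# behavioral reports from the coherence-dependent von Mises mixture,
# a direction-tuned voxel population, trial-wise response amplitudes and
# gaze traces. At zero coherence the voxel drive follows the (guessed)
# report, which is what later makes choice-related decoding possible.
#
# Outputs: results/events.tsv, results/voxels.tsv, results/betas.tsv,
#          results/gaze.tsv

library(gprdecode)

dir.create("results", showWarnings = FALSE)
seed <- 20

trials <- generate_trial_sequence(n_runs = 10, trials_per_coherence = 16,
                                  seed = seed)
trials <- simulate_reports(trials, default_report_mixture(),
                           zero_latent = "report", seed = seed + 1)

voxels <- generate_voxel_population(
  n_voxels = 60, grid_shape = c(6, 6, 6),
  tuning_spec = list(informative_fraction = 0.8,
                     noise_sd_range = c(0.2, 0.4)),
  seed = seed + 2)

betas <- simulate_betas(trials, voxels, seed = seed + 3)
gaze <- simulate_gaze(trials, fixation_sd = 0.15, sampling_rate = 250,
                      seed = seed + 4)

write_trial_table(trials, "results/events.tsv")
write.table(voxels, "results/voxels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_beta_matrix(betas, "results/betas.tsv")
write_gaze_record(gaze, "results/gaze.tsv")

cat(sprintf("simulated %d trials, %d voxels (%d informative), %d gaze samples\n",
            nrow(trials), nrow(voxels), sum(voxels$informative), nrow(gaze)))
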