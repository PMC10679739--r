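#!/usr/bin/env Rscript
# Stage 5: searchlight maximum-likelihood reconstruction.
#
# Leave-one-run-out decoding of the presented direction (stimulus label)
# and the reported direction (report label) at full and zero coherence,
# using the voxel cluster's FDTFs and the shrinkage-regularized residual
# covariance. Accuracy is summarized as mean FCA and BFCA per condition;
# chance is 50%.
#
# Inputs:  results/betas.tsv
# Outputs: results/reconstruction.csv, results/accuracy_summary.csv

library(gprdecode)

betas <- read_beta_matrix("results/betas.tsv")

results <- run_reconstruction(betas,
                              coherences = c("full", "zero"),
                              labels = c("stimulus", "report"),
                              regularizer = "arctan")
write.csv(results, "results/reconstruction.csv", row.names = FALSE)

summary_df <- aggregate_accuracy(results)
write.csv(summary_df, "results/accuracy_summary.csv", row.names = FALSE)

print(summary_df, digits = 4)
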