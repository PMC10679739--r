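#!/usr/bin/env Rscript
# Stage 6: cross-condition generalization.
#
# Trains the reconstruction model on the reported direction at zero
# coherence (pure guessing, so the training labels carry no stimulus
# information) and decodes the presented direction at full coherence, and
# vice versa. Generalization of the guessing-trained model to real stimuli
# indicates that internally generated choices and external stimuli share a
# representational format in the voxel patterns — which is how this
# generator was built (the zero-coherence voxel drive follows the report).
#
# Inputs:  results/betas.tsv
# Outputs: results/generalization.csv

library(gprdecode)

betas <- read_beta_matrix("results/betas.tsv")

pairs <- list(
  list(model = list(label = "report", coherence = "zero"),
       data = list(label = "stimulus", coherence = "full")),
  list(model = list(label = "stimulus", coherence = "full"),
       data = list(label = "report", coherence = "zero")))

rows <- lapply(pairs, function(p) {
  cr <- cross_predict(betas, p$model, p$data, regularizer = "arctan")
  data.frame(model_label = p$model$label, model_coherence = p$model$coherence,
             data_label = p$data$label, data_coherence = p$data$coherence,
             bfca = cr$bfca, mean_fca = cr$mean_fca, n_trials = cr$n_trials)
})
gen <- do.call(rbind, rows)
write.csv(gen, "results/generalization.csv", row.names = FALSE)

print(gen, digits = 4)
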