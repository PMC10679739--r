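#!/usr/bin/env Rscript
# Stage 3: behavioral screening.
#
# Fits the three-component von Mises mixture (target / opposite / guess)
# to the signed report errors at each coherence and applies the two
# pre-scanning exclusion rules on full-coherence trials: 95th-percentile
# absolute deviation <= 36.5 degrees and fitted opposite-report rate
# (ROOD) <= 5%.
#
# Inputs:  results/events.tsv
# Outputs: results/behavior_summary.csv, results/screening.csv

library(gprdecode)

trials <- read_trial_table("results/events.tsv")
trials <- trials[trials$valid & is.finite(trials$theta_r), ]

rows <- lapply(unique(trials$coherence), function(coh) {
  sub <- trials[trials$coherence == coh, ]
  fit <- fit_vmmm(signed_circular_diff(sub$theta_s, sub$theta_r), seed = 1)
  data.frame(coherence = coh, n_trials = fit$n_trials,
             w_detect = fit$w_detect, w_opposite = fit$w_opposite,
             w_guess = fit$w_guess, kappa = fit$kappa,
             mean_fca = score_fca(sub$theta_s, sub$theta_r))
})
behavior <- do.call(rbind, rows)
write.csv(behavior, "results/behavior_summary.csv", row.names = FALSE)

screening <- screen_participant(trials[trials$coherence == "full", ])
write.csv(data.frame(p95_deviation = screening$p95_deviation,
                     rood_rate = screening$rood_rate,
                     include = screening$include,
                     reasons = paste(screening$reasons, collapse = "; ")),
          "results/screening.csv", row.names = FALSE)

print(behavior, digits = 3)
print(screening)
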