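# gprdecode

Continuous motion-direction encoding and decoding for fMRI-style data.

Human behavioral and imaging studies of motion perception increasingly use
*continuous* report tasks: the participant sees a field of moving dots whose
coherence (fraction of coherently moving dots) controls the strength of the
motion evidence, and then reproduces the perceived direction on a full
0–360° circle instead of picking from discrete options. Decoding such data
requires models that treat direction as a circular continuum. This package
implements the full workflow on synthetic data:

- **Session simulation** — pseudo-randomized trial sequences (hidden
  45° randomization bins, run-length constraints, geometric ITIs),
  coherence-dependent behavioral reports from a von Mises mixture,
  direction-tuned voxel populations, trial-wise response amplitudes,
  BOLD series with a canonical HRF, and gaze traces.
- **Quality control** — kernel-density run-noise thresholds on gaze SD and
  rejection of trials with sustained fixation breaks (> 2 dva for
  > 200 ms).
- **Behavioral screening** — a three-component von Mises mixture model
  (vMMM: target, opposite, guessing) whose opposite weight quantifies the
  rate of reports of opposite direction (ROOD).
- **Encoding** — each voxel's full distribution tuning function (FDTF): a
  Gaussian-process regression with a periodic (exp-sine-squared) kernel,
  giving a predictive mean *and* variance for every direction.
- **Decoding** — searchlight maximum-likelihood reconstruction: the
  presented (or reported) direction of a held-out trial is the grid argmax
  of a multivariate normal likelihood built from the member voxels' FDTFs
  and a shrinkage-regularized residual covariance.
- **Evaluation** — feature-continuous accuracy (FCA; 0° error → 100 %,
  90° → 50 % chance, 180° → 0 %) and its balanced variant BFCA
  (trapezoid-integrated over the true-direction circle), plus
  cross-condition generalization.

## Core model

Voxel responses to direction θ are modeled as a GP with periodic kernel

```
k(θ, θ') = σ_f² · exp( −2 sin²((θ − θ')/2) / ℓ² )
```

with signal variance σ_f², length scale ℓ and noise variance σ_n²
maximized in the marginal likelihood per voxel. For a searchlight of v
voxels and t training trials, the residual covariance Σ̂ = R'R / t is
shrunk toward its diagonal, Σ = (1 − r) Σ̂ + r diag(Σ̂), with
r = 1/2 + arctan(ln(v/t))/π (a logistic alternative r = (v/t)/(1 + v/t) is
provided, as is the defective arctan form without the 1/2 offset — see the
vignette). A test trial's direction is decoded as the argmax over a 1°
grid of the MVN log likelihood of its amplitude pattern.

## Worked example

```r
library(gprdecode)

# 1. simulate a session: 6 runs, 16 trials per coherence per run
trials <- generate_trial_sequence(n_runs = 6, trials_per_coherence = 16,
                                  coherence_levels = c(zero = 0, full = 1),
                                  seed = 42)
# a precise participant: 98% detection (kappa = 25), 1% opposite, 1% guess;
# zero coherence always forces guessing
mixture <- data.frame(coherence = c("zero", "full"),
                      w_detect = c(0, 0.98), w_opposite = c(0, 0.01),
                      w_guess = c(1, 0.01), kappa = c(0, 25))
trials <- simulate_reports(trials, mixture, zero_latent = "report", seed = 43)

# 2. a direction-tuned voxel population and trial-wise amplitudes
voxels <- generate_voxel_population(30, c(5, 5, 5),
                                    tuning_spec = list(noise_sd_range = c(0.1, 0.3)),
                                    seed = 44)
betas <- simulate_betas(trials, voxels, seed = 45)

# 3. behavioral screening on full-coherence trials
screen_participant(trials[trials$coherence == "full", ])
#> screening: p95 = 24.3 deg, ROOD = 0.021 -> include

# 4. leave-one-run-out reconstruction of the presented direction
res <- run_reconstruction(betas, coherences = "full", labels = "stimulus")
aggregate_accuracy(res)
#>   group coherence label_type mean_fca     bfca n_trials chance
#> 1   all      full   stimulus 98.07132 98.09949       96     50

# 5. train on guessed reports at zero coherence, decode the stimulus
cross <- cross_predict(betas,
                       model_condition = list(label = "report", coherence = "zero"),
                       data_condition = list(label = "stimulus", coherence = "full"))
round(cross$bfca, 2)
#> [1] 98.03
```

The last number is the interesting one: the model was trained purely on
*guessed* directions at zero coherence (the labels carry no stimulus
information), yet it reconstructs real stimuli at full coherence — because
this generator ties the zero-coherence voxel drive to the internally
generated choice (`zero_latent = "report"`), internal choices and external
stimuli share one representational format. Setting
`zero_latent = "independent"` breaks that link and drops the
cross-prediction to chance.

## Analysis workflow

The `analysis/` directory holds the numbered end-to-end workflow; each
script is a thin driver over the package functions and writes its tables to
`results/`:

| script | writes |
|---|---|
| `01_simulate.R` | `events.tsv`, `voxels.tsv`, `betas.tsv`, `gaze.tsv` |
| `02_qc.R` | `qc_summary.csv`, updates the `valid` column of `events.tsv` |
| `03_behavior.R` | `behavior_summary.csv`, `screening.csv` |
| `04_encoding.R` | `encoding_summary.csv` |
| `05_decoding.R` | `reconstruction.csv`, `accuracy_summary.csv` |
| `06_generalization.R` | `generalization.csv` |

Run them in order from the repository root:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`run_pipeline()` packages the same stages as a single seeded, manifest-
writing call.

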