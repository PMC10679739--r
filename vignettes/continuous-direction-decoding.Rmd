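---
title: "Continuous motion-direction encoding and decoding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous motion-direction encoding and decoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gprdecode)
```

This vignette documents the models, the parameter choices and the
numerical decisions behind `gprdecode`. The package simulates and analyzes
a continuous motion-direction experiment: on each trial a participant
views a random dot kinematogram at one of several motion coherences and
reproduces the perceived direction on the full circle; voxel-level
responses are then used to reconstruct the presented (or reported)
direction trial by trial.

## 1. Session design

`generate_trial_sequence()` builds the trial table. Directions are not
drawn freely: the circle is divided into eight hidden 45° randomization
bins (bin 1 centered on 0°, so its edges are 337.5° and 22.5°), and
session-level balance is enforced by allocating each coherence an equal
count per bin before drawing the exact direction uniformly *within* the
assigned bin. Two run-length constraints keep the sequence locally
unpredictable: the same bin never repeats more than twice in a row, the
same coherence never more than three times. These are satisfied by
sequential constrained sampling with restarts; with a single coherence
level the coherence constraint is vacuous and is skipped. A trial lasts
0.5 s fixation + 2 s stimulus + 7.5 s report; inter-trial intervals are
drawn from {3, 5, 7, 9} s with geometrically halving probabilities, so
short gaps dominate while long ones still occur (the standard trade-off
between design efficiency and trial-wise estimability).

```{r design}
trials <- generate_trial_sequence(n_runs = 2, trials_per_coherence = 16,
                                  seed = 1)
table(trials$run, trials$coherence)
```

## 2. Behavioral generator and the vMMM

Reports are generated by `simulate_reports()` from a per-coherence mixture
of three processes: detection (von Mises around the target), opposite
reports (von Mises around target + 180°, same concentration) and guessing
(circular uniform). The same mixture is the *measurement* model:
`fit_vmmm()` recovers the weights and concentration by maximum likelihood
(Nelder–Mead in softmax/log space, 10 seeded restarts), and
`screen_participant()` applies the two exclusion rules used before
scanning: 95th-percentile absolute error ≤ 36.5° and fitted
opposite-report rate (ROOD) ≤ 5%.

Two deliberate semantics:

- **Zero coherence forces guessing.** Whatever mixture is supplied, trials
  at coherence 0 draw reports uniformly — there is no signal to detect.
- **The zero-coherence voxel drive is configurable.** `zero_latent =
  "report"` (default) makes the generative direction of the voxel response
  equal the guessed report, modelling internally generated direction
  signals; `"independent"` decouples them. Cross-decoding between
  zero-coherence reports and full-coherence stimuli succeeds under the
  first and collapses to chance under the second, which is exactly the
  contrast the generalization analysis is designed to detect.

A caveat worth knowing: at κ → 0 a von Mises *is* the uniform density, so
on uniform data (e.g. zero coherence) the vMMM weights are not
identifiable — only the fitted density is. Screening therefore uses
full-coherence trials only.

## 3. Voxels, BOLD and trial-wise amplitudes

`generate_voxel_population()` places voxels on an integer lattice with
stratified preferred directions and log-uniform-ish tuning parameters;
tuning curves are exponentiated-cosine bumps
`baseline + amplitude · exp(width · (cos(θ − phase) − 1))`, optionally with
a second harmonic. `simulate_betas()` adds i.i.d. Gaussian trial noise.
For tests of the GLM path, `simulate_bold_run()` renders a full BOLD
series: 2 s boxcars convolved with the canonical double-gamma HRF
(shape 6 and 16, ratio 1/6) on a 0.1 s grid, AR(1) scan noise, motion
nuisance with optional leakage, and the voxel baseline as a constant
series offset (absorbed by the GLM intercept, not by the trial
regressors). `estimate_trial_betas()` is a least-squares-all GLM with one
regressor per trial plus six motion parameters and an intercept, with an
explicit rank check naming collinear columns.

## 4. Encoding: cyclic GP tuning functions

Each voxel's full distribution tuning function (FDTF) is a GP posterior
with the periodic exp-sine-squared kernel

$$k(\theta, \theta') = \sigma_f^2 \exp\!\left(-\,2\sin^2\!\big((\theta-\theta')/2\big)\,/\,\ell^2\right),$$

angles in radians, plus noise variance $\sigma_n^2$ on the diagonal.
Hyperparameters maximize the log marginal likelihood; `fit_voxel_gpr()`
optimizes in log space by L-BFGS-B with analytic gradients and seeded
restarts, bounding $\ell \in [0.05, 10]$ and both variances in
$[10^{-6}, 10]\cdot\mathrm{var}(y)$. Degenerate (constant) voxels fall
back to an explicit flat FDTF. The posterior mean and variance are cached
on the 1°–360° grid used for decoding.

**Batched fitting.** A searchlight fit is one GP per member voxel, but
within a cross-validation fold all voxels share the same training
directions, hence the same kernel matrix up to scale. `fit_fdtf_batch()`
profiles out $\sigma_f^2$ in closed form
($\hat\sigma_f^2 = y^\top (C(\ell) + \rho I)^{-1} y / n$, with
$\rho = \sigma_n^2/\sigma_f^2$) and shares a single Cholesky factorization
per $(\ell, \rho)$ grid point across all voxels (20 × 16 log-spaced grid),
followed by per-voxel gradient refinement. This is an order of magnitude
faster than independent fits at searchlight scale (257 voxels) and agrees
with the per-voxel fitter within test tolerances.

## 5. Decoding: searchlight maximum likelihood

For a searchlight (radius 4 voxels → 257 members in the volume interior),
the decoder models a test trial's amplitude pattern $b$ as multivariate
normal around the member FDTFs' predictive means $g(\theta)$:

$$\hat\theta = \arg\max_{\theta \in \{1°,\dots,360°\}}
\; \log \mathcal{N}\big(b \mid g(\theta), \Sigma\big).$$

$\Sigma$ is the training-residual covariance $R^\top R / t$ shrunk toward
its diagonal, $\Sigma = (1-r)\hat\Sigma + r\,\mathrm{diag}(\hat\Sigma)$,
which guarantees invertibility when voxels outnumber trials. The GP noise
variance is *not* added on top: the residuals already carry it, so adding
it again would double-count. The Cholesky factor of $\Sigma$ is computed
once per fold and reused for all grid points and test trials
(`backsolve`, no explicit inverse). Ties in the profile resolve to the
smallest angle and 360° is reported as 0°.

**The mixing coefficient.** The shrinkage weight is a function of the
voxel-to-trial ratio $x = v/t$. Three forms are implemented:

```{r mixing}
x <- c(0.01, 1, 100)
rbind(logistic = mixing_coefficient(x, 1, "logistic"),
      arctan = mixing_coefficient(x, 1, "arctan"),
      printed = mixing_coefficient(x, 1, "printed-arctan"))
```

`logistic` is $x/(1+x)$; `arctan` is $1/2 + \arctan(\ln x)/\pi$. Both are
strictly increasing with $r(1) = 1/2$ and limits 0 and 1 — the properties
a shrinkage weight must have. The third form, $\arctan(\ln x)/\pi$
*without* the offset, is sometimes quoted for this estimator, but as the
output above shows it yields $r(1)=0$, goes negative for $v<t$ and is
bounded by 1/2; it is kept only as `"printed-arctan"` for comparison, and
a test documents the violation. The default is `arctan`.

## 6. Evaluation: FCA and BFCA

Feature-continuous accuracy maps the absolute circular error (shortest
arc, in [0°, 180°]) linearly to a percentage:
$\mathrm{FCA} = (180 - |\Delta x|)/180 \times 100$, so 0° → 100 %,
90° → 50 % (the guessing level) and 180° → 0 %. BFCA integrates per-trial
FCA over the *sorted true directions* by the trapezoid rule, averaging
duplicates and re-appending the first point at θ + 360° to close the
circle, divided by 360. This removes the spurious accuracy a constant
decoder earns from unbalanced labels; with balanced labels BFCA ≈ FCA.
The circular closure matters: without it the wrap-around segment of the
circle is simply missing from the integral.

## 7. Gaze quality control

`apply_fixation_qc()` combines two rules. Run-level: the per-run gaze SD
(`sqrt(var(x) + var(y))`, valid samples only) must not exceed the 90 %
point of a kernel density estimate (`stats::density`, normal-reference
bandwidth) of a reference SD distribution — in a multi-subject setting the
pooled runs; the threshold is clamped to the sample range because the KDE
CDF extends past it. Trial-level: a trial is rejected if gaze leaves a
2 dva radius *continuously* for more than 200 ms during the 2 s stimulus
(strict inequalities; blinks/invalid samples interrupt an excursion rather
than extending it; trials without coverage are "unscorable" rather than
rejected).

## 8. Problem sizes, determinism and limitations

The tests run a seeded single-subject cohort (10 runs × 48 trials,
257-voxel searchlight cluster on a 9³ lattice) in a few minutes on one
CPU; the numbered `analysis/` scripts use a 60-voxel population for a
faster narrative run. `run_pipeline()` derives a deterministic sub-seed
per stage from the master seed and writes a manifest with an md5 hash of
the configuration, so identical configurations reproduce bitwise-identical
outputs.

Known simplifications of the generator: trial noise is Gaussian and
i.i.d. across voxels (no spatial noise correlations, so shrinkage is
exercised structurally rather than by realistic correlation patterns); the
BOLD path is used for GLM validation rather than feeding the decoder
end-to-end; gaze is simulated per stimulation window only; there is no
volumetric (NIfTI) serialization — voxel coordinates live in a plain
table. Tuning curves are unimodal-plus-harmonic, which matches the
encoding model's assumptions; real voxels are messier, and the recovery
numbers here are upper bounds, not forecasts for empirical data.
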