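# Independent brute-force oracles and small fixture builders.
# The oracles use only dense base-R linear algebra (solve, determinant)
# and explicit formulas, independent of the package's Cholesky paths.

# dense GP posterior at `grid` given hyperparameters and training data
gp_posterior_oracle <- function(y, theta, ell, sf2, sn2, grid) {
  k <- function(a, b) sf2 * exp(-2 * sin(((a - b) * pi / 180) / 2)^2 / ell^2)
  n <- length(y)
  K <- outer(theta, theta, k) + diag(sn2, n)
  Ks <- outer(grid, theta, k)
  yc <- y - mean(y)
  Kinv <- solve(K)
  mean <- mean(y) + as.numeric(Ks %*% Kinv %*% yc)
  var_f <- sf2 - rowSums((Ks %*% Kinv) * Ks)
  list(mean = mean, var = pmax(var_f, 0) + sn2)
}

# dense GP negative log marginal likelihood
gp_nlml_oracle <- function(y, theta, ell, sf2, sn2) {
  k <- function(a, b) sf2 * exp(-2 * sin(((a - b) * pi / 180) / 2)^2 / ell^2)
  n <- length(y)
  K <- outer(theta, theta, k) + diag(sn2, n)
  yc <- y - mean(y)
  0.5 * as.numeric(t(yc) %*% solve(K) %*% yc) +
    0.5 * as.numeric(determinant(K, logarithm = TRUE)$modulus) +
    0.5 * n * log(2 * pi)
}

# element-by-element residual covariance
residual_covariance_oracle <- function(B, H) {
  R <- B - H
  t_n <- nrow(R); v <- ncol(R)
  S <- matrix(0, v, v)
  for (a in seq_len(v)) for (b in seq_len(v))
    S[a, b] <- sum(R[, a] * R[, b]) / t_n
  S
}

# multivariate normal log density from the textbook formula
mvn_loglik_oracle <- function(x, mu, Sigma) {
  v <- length(x)
  d <- x - mu
  -0.5 * (as.numeric(t(d) %*% solve(Sigma) %*% d) +
          as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
          v * log(2 * pi))
}

# two cosine-tuned voxels with phases 0 and 90 degrees: the pair of mean
# responses identifies the direction uniquely on the circle
two_voxel_population <- function(noise_sd = 0) {
  data.frame(
    voxel = 1:2, x = 1:2, y = 1L, z = 1L, roi_label = "ROI",
    tuning_amplitude = c(1, 1), tuning_width = c(0.5, 0.5),
    tuning_phase = c(0, 90), second_harmonic = 0,
    baseline = 0, noise_sd = noise_sd, informative = TRUE)
}

# small decodable cohort: n_runs runs, 16 trials/coherence/run, an
# informative voxel cluster with low noise
make_small_cohort <- function(seed = 1, n_runs = 4, n_voxels = 12,
                              noise_sd = c(0.05, 0.15),
                              zero_latent = "report") {
  tt <- generate_trial_sequence(n_runs, 16, seed = seed)
  tt <- simulate_reports(tt, zero_latent = zero_latent, seed = seed + 1)
  vox <- generate_voxel_population(
    n_voxels, c(6, 6, 6),
    tuning_spec = list(noise_sd_range = noise_sd), seed = seed + 2)
  betas <- simulate_betas(tt, vox, seed = seed + 3)
  list(trials = tt, voxels = vox, betas = betas)
}

max_run_length <- function(x) max(rle(as.character(x))$lengths)
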