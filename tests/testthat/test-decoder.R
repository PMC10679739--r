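# a noiseless, fully decodable two-voxel setup shared by several tests
noiseless_decoder <- function(seed = 11, n_runs = 4) {
  tt <- generate_trial_sequence(n_runs, 16,
                                coherence_levels = c(full = 1), seed = seed)
  tt <- simulate_reports(tt, data.frame(coherence = "full", w_detect = 1,
                                        w_opposite = 0, w_guess = 0,
                                        kappa = 1e6), seed = seed + 1)
  vox <- two_voxel_population(noise_sd = 0)
  betas <- simulate_betas(tt, vox, seed = seed + 2)
  list(trials = tt, voxels = vox, betas = betas)
}

test_that("searchlight extraction has the expected geometry", {
  grid <- as.matrix(expand.grid(x = 1:9, y = 1:9, z = 1:9))
  center <- which(grid[, 1] == 5 & grid[, 2] == 5 & grid[, 3] == 5)
  members <- extract_searchlight(grid, center, radius = 4)
  expect_length(members, 257)
  expect_true(center %in% members)
  # radius 0 is just the center
  expect_equal(extract_searchlight(grid, center, radius = 0), center)
  # corner center: sphere clipped at the borders, so fewer members
  corner <- which(grid[, 1] == 1 & grid[, 2] == 1 & grid[, 3] == 1)
  expect_lt(length(extract_searchlight(grid, corner, radius = 4)), 257)
  # every member is within the radius, every non-member beyond it
  d2 <- colSums((t(grid) - grid[center, ])^2)
  expect_true(all(d2[members] <= 16 + 1e-9))
  expect_true(all(d2[-members] > 16))
})

test_that("residual covariance matches the elementwise oracle", {
  set.seed(12)
  B <- matrix(rnorm(15), 5, 3)
  P <- matrix(rnorm(15), 5, 3)
  S <- residual_covariance(B, P)
  expect_lt(max(abs(S - residual_covariance_oracle(B, P))), 1e-10)
  expect_equal(S, t(S))
  expect_true(all(eigen(S, symmetric = TRUE, only.values = TRUE)$values
                  >= -1e-12))
})

test_that("mixing coefficients have the stated properties", {
  for (m in c("logistic", "arctan")) {
    expect_equal(mixing_coefficient(100, 100, m), 0.5)
    # strictly increasing in v/t
    x <- 10^seq(-6, 6, by = 0.5)
    r <- mixing_coefficient(x, 1, m)
    expect_true(all(diff(r) > 0))
    expect_true(all(r > 0 & r < 1))
  }
  # the logistic map reaches its limits fast, the arctan map only
  # logarithmically
  expect_lt(mixing_coefficient(1, 1e8, "logistic"), 1e-7)
  expect_gt(mixing_coefficient(1e8, 1, "logistic"), 1 - 1e-7)
  expect_lt(mixing_coefficient(1, 1e8, "arctan"), 0.02)
  expect_gt(mixing_coefficient(1e8, 1, "arctan"), 0.98)
  expect_equal(mixing_coefficient(3, 1, "logistic"), 0.75)
  # the printed arctan form violates the stated limits: r(1) = 0,
  # negative for v < t, and bounded by 1/2 rather than 1
  expect_equal(mixing_coefficient(1, 1, "printed-arctan"), 0)
  expect_lt(mixing_coefficient(1, 10, "printed-arctan"), 0)
  expect_lt(mixing_coefficient(1e12, 1, "printed-arctan"), 0.5)
  expect_error(mixing_coefficient(0, 1), "positive")
})

test_that("shrinkage behaves at the endpoints and bounds eigenvalues", {
  set.seed(13)
  A <- matrix(rnorm(40), 10, 4)
  S <- crossprod(A) / 10
  expect_equal(shrink_covariance(S, 0), S)
  expect_equal(shrink_covariance(S, 1), diag(diag(S), 4))
  Sh <- shrink_covariance(S, 0.3)
  expect_equal(diag(Sh), diag(S))
  ev <- eigen(Sh, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= 0.3 * min(diag(S)) *
                    min(eigen(diag(4), only.values = TRUE)$values) - 1e-12))
  # rank-deficient raw covariance becomes positive definite under shrinkage
  B <- matrix(rnorm(12), 2, 6)   # 2 trials, 6 voxels: rank <= 2
  S2 <- crossprod(B) / 2
  ev2 <- eigen(shrink_covariance(S2, 0.5), symmetric = TRUE,
               only.values = TRUE)$values
  expect_true(all(ev2 > 0))
  expect_error(shrink_covariance(S, 1.2), "r <= 1")
})

test_that("likelihood profile matches the textbook MVN oracle", {
  # a small, well-conditioned instance: 20 trials, 4 voxels, real noise
  set.seed(19)
  theta <- runif(20, 0, 360)
  B <- outer(theta * pi / 180, c(0, 0.5, 1, 1.5) * pi,
             function(a, p) cos(a - p)) + matrix(rnorm(80, sd = 0.3), 20, 4)
  model <- fit_searchlight_model(B, theta)
  beta_row <- B[1, ] + rnorm(4, sd = 0.3)
  prof <- loglik_profile(beta_row, model)
  oracle <- vapply(seq_along(model$grid), function(g)
    mvn_loglik_oracle(beta_row, model$G[g, ], model$Sigma), numeric(1))
  expect_lt(max(abs(prof - oracle)), 1e-6)
})

test_that("decode_trial takes the argmax with first-point tie-breaking", {
  expect_equal(decode_trial(c(-5, -1, -3), grid = c(10, 20, 30)), 20)
  expect_equal(decode_trial(rep(0, 360)), 1)      # tie -> smallest angle
  expect_equal(decode_trial(c(rep(-1, 359), 0)), 0)  # 360 reported as 0
  expect_error(decode_trial(c(0, NA, 1)), "finite")
})

test_that("noiseless two-voxel decoding is exact over a full sweep", {
  nd <- noiseless_decoder()
  res <- run_reconstruction(nd$betas, labels = "stimulus")
  expect_equal(nrow(res), nrow(nd$trials))       # each trial decoded once
  expect_equal(anyDuplicated(res$trial_id), 0L)
  dev <- circular_deviation(res$theta_true, res$theta_hat)
  # grid resolution is 1 degree, so errors are bounded by rounding
  expect_lt(max(dev), 1)
  expect_gt(score_bfca(res$theta_true, res$theta_hat), 99.5)
})

test_that("decoding is equivariant to a global label rotation", {
  nd <- noiseless_decoder(seed = 14, n_runs = 2)
  tt <- nd$trials
  folds <- make_cv_folds(tt)
  f <- folds[[1]]
  tr <- match(f$train_ids, tt$trial_id)
  te <- match(f$test_ids, tt$trial_id)
  model0 <- fit_searchlight_model(nd$betas$values[tr, ], tt$theta_s[tr])
  delta <- 90
  model1 <- fit_searchlight_model(nd$betas$values[tr, ],
                                  wrap360(tt$theta_s[tr] + delta))
  hat0 <- vapply(te, function(i)
    decode_trial(loglik_profile(nd$betas$values[i, ], model0)), numeric(1))
  hat1 <- vapply(te, function(i)
    decode_trial(loglik_profile(nd$betas$values[i, ], model1)), numeric(1))
  expect_true(all(circular_deviation(wrap360(hat0 + delta), hat1) <= 1))
})

test_that("shuffled training labels destroy decodability", {
  sc <- make_small_cohort(seed = 15, n_runs = 6, n_voxels = 12,
                          noise_sd = c(0.05, 0.15))
  tt <- sc$trials
  full <- tt[tt$coherence == "full", ]
  set.seed(16)
  shuf <- tt
  idx <- shuf$coherence == "full"
  shuf$theta_s[idx] <- sample(shuf$theta_s[idx])
  betas_shuf <- sc$betas
  betas_shuf$trials <- shuf
  res <- run_reconstruction(betas_shuf, coherences = "full",
                            labels = "stimulus")
  acc <- score_fca(res$theta_true, res$theta_hat)
  # 3 SE of mean FCA at n = 96 under chance is ~9
  expect_lt(abs(acc - 50), 10)
})
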