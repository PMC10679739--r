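test_that("the periodic kernel has the defining properties", {
  expect_equal(cyclic_kernel(40, 40, ell = 0.7, sf2 = 3)[1], 3)
  expect_equal(cyclic_kernel(0, 360, ell = 0.7, sf2 = 3),
               cyclic_kernel(0, 0, ell = 0.7, sf2 = 3))
  # strictly decreasing in circular distance up to 180 degrees
  k <- cyclic_kernel(0, seq(0, 180, by = 5), ell = 1)
  expect_true(all(diff(as.numeric(k)) < 0))
  expect_error(cyclic_kernel(0, 10, ell = 0), "ell")
})

test_that("leave-one-run-out folds partition the valid trials", {
  tt <- generate_trial_sequence(10, 16, coherence_levels = c(full = 1),
                                seed = 2)
  folds <- make_cv_folds(tt)
  expect_length(folds, 10)
  expect_true(all(vapply(folds, function(f) length(f$train_ids),
                         numeric(1)) == 144))
  all_test <- sort(unlist(lapply(folds, `[[`, "test_ids")))
  expect_equal(all_test, tt$trial_id)  # disjoint and exhaustive
  for (f in folds)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
  # run appearing only as training once trials are excluded
  tt2 <- tt
  tt2$valid[tt2$run == 3][1:5] <- FALSE
  folds2 <- make_cv_folds(tt2)
  f3 <- folds2[[3]]
  expect_equal(f3$run, 3)
  expect_length(f3$test_ids, 11)
  # two runs give two folds
  expect_length(make_cv_folds(tt[tt$run <= 2, ]), 2)
  expect_error(make_cv_folds(tt[tt$run == 1, ]), "at least 2 runs")
})

test_that("constant responses give a flat tuning function", {
  m <- fit_voxel_gpr(rep(3.2, 30), runif(30, 0, 360), seed = 1)
  expect_true(all(abs(m$grid_mean - 3.2) < 1e-8))
  expect_lt(m$sf2, 1e-8)
})

test_that("noiseless cosine tuning is recovered within 2% RMS", {
  set.seed(4)
  theta <- runif(144, 0, 360)
  amp <- 2
  y <- amp * cos(theta * pi / 180)
  m <- fit_voxel_gpr(y, theta, seed = 1)
  p <- predict_fdtf(m, 1:360)
  rms <- sqrt(mean((p$mean - amp * cos((1:360) * pi / 180))^2))
  expect_lt(rms / amp, 0.02)
  # periodic continuity: prediction at 360 equals prediction at 0 (=grid wrap)
  p2 <- predict_fdtf(m, c(0, 360))
  expect_equal(p2$mean[1], p2$mean[2], tolerance = 1e-10)
})

test_that("white-noise responses put the variance into the noise term", {
  set.seed(5)
  y <- rnorm(144, sd = 0.7)
  m <- fit_voxel_gpr(y, runif(144, 0, 360), seed = 1)
  expect_lt(abs(m$sn2 - var(y)) / var(y), 0.2)
})

test_that("the default prediction grid has 360 points and matches the cache", {
  set.seed(6)
  theta <- runif(40, 0, 360)
  y <- sin(theta * pi / 180) + rnorm(40, sd = 0.1)
  m <- fit_voxel_gpr(y, theta, seed = 1)
  expect_length(m$grid_mean, 360)
  expect_length(m$grid_var, 360)
  expect_true(all(m$grid_var > 0))
})

test_that("GP posterior matches the dense-matrix oracle within 1e-6", {
  set.seed(7)
  theta <- runif(20, 0, 360)
  y <- cos(theta * pi / 180) + rnorm(20, sd = 0.2)
  m <- fit_voxel_gpr(y, theta, seed = 1)
  grid <- seq(5, 355, by = 10)
  p <- predict_fdtf(m, grid)
  o <- gp_posterior_oracle(y, theta, m$ell, m$sf2, m$sn2 + 1e-10 * var(y),
                           grid)
  expect_lt(max(abs(p$mean - o$mean)), 1e-6)
  expect_lt(max(abs(p$var - o$var)), 1e-6)
})

test_that("interpolation limit: near-zero noise reproduces training data", {
  set.seed(8)
  theta <- seq(10, 350, length.out = 18)
  y <- cos(theta * pi / 180)
  m <- fit_voxel_gpr(y, theta, seed = 1)
  p <- predict_fdtf(m, theta)
  expect_lt(max(abs(p$mean - y)), 0.02)
})

test_that("fitted hyperparameters beat random draws in marginal likelihood", {
  set.seed(9)
  theta <- runif(60, 0, 360)
  y <- 1.5 * cos((theta - 40) * pi / 180) + rnorm(60, sd = 0.3)
  m <- fit_voxel_gpr(y, theta, seed = 1)
  nlml_fit <- gp_nlml_oracle(y, theta, m$ell, m$sf2, m$sn2)
  expect_equal(nlml_fit, m$nlml, tolerance = 1e-6)
  vy <- var(y)
  draws <- matrix(c(exp(runif(100, log(0.05), log(10))),
                    exp(runif(100, log(1e-6 * vy), log(10 * vy))),
                    exp(runif(100, log(1e-6 * vy), log(10 * vy)))),
                  ncol = 3)
  nlml_rand <- apply(draws, 1, function(p)
    gp_nlml_oracle(y, theta, p[1], p[2], p[3]))
  expect_true(all(nlml_fit <= nlml_rand + 1e-8))
})

test_that("tuning estimates are invariant to a global rotation", {
  set.seed(10)
  theta <- runif(80, 0, 360)
  y <- cos(theta * pi / 180) + rnorm(80, sd = 0.2)
  delta <- 73
  m0 <- fit_voxel_gpr(y, theta, seed = 1)
  m1 <- fit_voxel_gpr(y, wrap360(theta + delta), seed = 1)
  grid <- 1:360
  p0 <- predict_fdtf(m0, grid)
  p1 <- predict_fdtf(m1, wrap360(grid + delta))
  expect_equal(p1$mean, p0$mean, tolerance = 1e-6)
})

test_that("batched fitting matches the per-voxel fitter", {
  sc <- make_small_cohort(seed = 3, n_runs = 3, n_voxels = 5)
  full <- sc$trials$coherence == "full"
  B <- sc$betas$values[full, ]
  theta <- sc$trials$theta_s[full]
  batch <- fit_fdtf_batch(B, theta)
  for (j in 1:5) {
    single <- fit_voxel_gpr(B[, j], theta, seed = 1)
    # both maximize the same marginal likelihood; optima agree closely
    expect_lt(abs(batch[[j]]$nlml - single$nlml),
              0.01 * max(1, abs(single$nlml)))
    expect_equal(batch[[j]]$grid_mean, single$grid_mean, tolerance = 0.05)
  }
})

test_that("too few training trials is an error", {
  expect_error(fit_voxel_gpr(rnorm(10), runif(10, 0, 360)), "at least 16")
  expect_error(fit_fdtf_batch(matrix(rnorm(20), 10, 2), runif(10, 0, 360)),
               "at least 16")
})
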