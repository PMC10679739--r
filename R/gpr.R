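#' Periodic (exp-sine-squared) covariance between directions
#'
#' The canonical cyclic kernel:
#' `k(a, b) = sf2 * exp(-2 * sin^2((a - b) / 2) / ell^2)`
#' with the angular difference in radians. It is symmetric, positive
#' definite and 360-degree periodic, and imposes no fixed number of tuning
#' channels — only smoothness on the circle.
#'
#' @param theta_a,theta_b directions in degrees (vectorized; a full cross
#'   covariance matrix is returned when both have length > 1).
#' @param ell kernel length-scale in radian units (> 0).
#' @param sf2 signal variance (>= 0).
#' @return covariance value(s): a matrix `length(theta_a)` x
#'   `length(theta_b)`.
#' @export
cyclic_kernel <- function(theta_a, theta_b, ell, sf2 = 1) {
  if (!is.finite(ell) || ell <= 0) stop("length-scale ell must be > 0")
  d <- deg2rad(outer(theta_a, theta_b, "-"))
  sf2 * exp(-2 * sin(d / 2)^2 / ell^2)
}

# sin^2 half-angle distance matrix for a set of directions (degrees)
sin2_half <- function(theta) {
  d <- deg2rad(outer(theta, theta, "-"))
  sin(d / 2)^2
}

#' Leave-one-run-out cross-validation folds
#'
#' One fold per run: the held-out run's valid trials form the test set,
#' all other runs' valid trials the training set. Runs without any valid
#' trial are skipped as test sets with a warning.
#'
#' @param trials a trial table (typically already restricted to one
#'   coherence level).
#' @return list (class `cv_folds`) of folds, each with `run`, `train_ids`
#'   and `test_ids` (trial ids).
#' @export
make_cv_folds <- function(trials) {
  ok <- trials$valid & is.finite(trials$theta_s)
  runs <- sort(unique(trials$run))
  if (length(runs) < 2) stop("need at least 2 runs for leave-one-run-out")
  folds <- list()
  for (r in runs) {
    test <- trials$trial_id[ok & trials$run == r]
    if (length(test) == 0) {
      warning("run ", r, " has no valid trials; skipped as a test set")
      next
    }
    folds[[length(folds) + 1]] <- list(
      run = r,
      train_ids = trials$trial_id[ok & trials$run != r],
      test_ids = test)
  }
  structure(folds, class = "cv_folds")
}

#' Fit a cyclic Gaussian-process tuning function for one voxel
#'
#' Estimates the full distribution tuning function (FDTF): a GP regression
#' of trial amplitudes on direction with the periodic kernel of
#' [cyclic_kernel()] plus i.i.d. Gaussian noise. Hyperparameters
#' (length-scale, signal variance, noise variance) maximize the log
#' marginal likelihood by L-BFGS-B in log space with analytic gradients
#' and seeded multi-start. Amplitudes are centered on the training mean;
#' the center is restored at prediction. If every start fails, a flat
#' model (signal variance 0) is returned with a warning.
#'
#' @param y trial amplitudes (>= 16 values).
#' @param theta training directions in degrees, aligned with `y`.
#' @param n_restarts optimizer restarts (the first start is a variance-split
#'   heuristic, the rest are seeded log-uniform draws within bounds).
#' @param seed integer seed for the restarts.
#' @param ell_bounds length-scale bounds (radian units).
#' @param grid directions at which to cache the posterior (degrees).
#' @param D optional precomputed `sin2_half(theta)` matrix (shared across
#'   voxels trained on the same directions).
#' @return an `fdtf` model: list with `ell`, `sf2`, `sn2`, `center`,
#'   `theta_train`, `alpha`, `U` (Cholesky factor of the training
#'   covariance), `nlml`, `grid`, `grid_mean`, `grid_var`, `n_train`.
#' @export
fit_voxel_gpr <- function(y, theta, n_restarts = 5, seed = 1,
                          ell_bounds = c(0.05, 10), grid = 1:360,
                          D = NULL) {
  n <- length(y)
  stopifnot(length(theta) == n)
  if (n < 16) stop("need at least 16 training trials (got ", n, ")")
  center <- mean(y)
  yc <- y - center
  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-12) {
    model <- flat_fdtf(center, max(vy, 1e-12), theta, grid, n)
    return(model)
  }
  if (is.null(D)) D <- sin2_half(theta)
  jitter <- 1e-10 * vy
  lower <- log(c(ell_bounds[1], 1e-6 * vy, 1e-6 * vy))
  upper <- log(c(ell_bounds[2], 10 * vy, 10 * vy))
  compute <- gp_objective(yc, D, jitter)

  set.seed(as.integer(seed))
  starts <- rbind(c(log(1), log(vy / 2), log(vy / 2)),
                  matrix(stats::runif(3 * max(n_restarts - 1, 0),
                                      rep(lower, each = max(n_restarts - 1, 0)),
                                      rep(upper, each = max(n_restarts - 1, 0))),
                         ncol = 3))[seq_len(n_restarts), , drop = FALSE]
  starts <- pmin(pmax(starts, rep(lower, each = nrow(starts))),
                 rep(upper, each = nrow(starts)))

  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[s, ], fn = function(p) compute(p)$nlml,
                   gr = function(p) compute(p)$grad,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    warning("GP hyperparameter optimization failed on all restarts; ",
            "falling back to a flat tuning model")
    return(flat_fdtf(center, vy, theta, grid, n))
  }
  build_fdtf(best$par, compute, center, theta, grid, n)
}

# Negative log marginal likelihood of the periodic-kernel GP with
# analytic gradients in (log ell, log sf2, log sn2). Returns a closure
# with a one-point cache since optim calls fn and gr in pairs at the same
# parameter value.
gp_objective <- function(yc, D, jitter) {
  n <- length(yc)
  cache <- new.env(parent = emptyenv())
  function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return(cache$val)
    ell <- exp(p[1]); sf2 <- exp(p[2]); sn2 <- exp(p[3])
    Kf <- sf2 * exp(-2 * D / ell^2)
    K <- Kf + diag(sn2 + jitter, n)
    U <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(U)) {
      cache$p <- p; cache$val <- list(nlml = 1e10, grad = rep(0, 3))
      return(cache$val)
    }
    alpha <- backsolve(U, backsolve(U, yc, transpose = TRUE))
    nlml <- 0.5 * sum(yc * alpha) + sum(log(diag(U))) +
      0.5 * n * log(2 * pi)
    Kinv <- chol2inv(U)
    A <- Kinv - tcrossprod(alpha)
    grad <- c(
      0.5 * sum(A * (Kf * (4 * D / ell^2))),  # d/d log ell
      0.5 * sum(A * Kf),                       # d/d log sf2
      0.5 * sn2 * sum(diag(A))                 # d/d log sn2
    )
    cache$p <- p
    cache$val <- list(nlml = nlml, grad = grad, U = U, alpha = alpha)
    cache$val
  }
}

# assemble an fdtf object from final hyperparameters (shared by the
# per-voxel and the batched fitters)
build_fdtf <- function(p, compute, center, theta, grid, n) {
  final <- compute(p)
  model <- structure(list(
    ell = exp(p[1]), sf2 = exp(p[2]), sn2 = exp(p[3]),
    center = center, theta_train = theta, alpha = final$alpha,
    U = final$U, nlml = final$nlml, n_train = n, flat = FALSE,
    grid = grid), class = "fdtf")
  pred <- predict_fdtf(model, grid)
  model$grid_mean <- pred$mean
  model$grid_var <- pred$var
  model
}

#' Fit cyclic GP tuning functions for many voxels sharing one design
#'
#' Batched counterpart of [fit_voxel_gpr()] for the searchlight stage,
#' where every voxel of a fold is trained on the same directions. The
#' marginal likelihood is first profiled on a shared grid: for each
#' (length-scale, noise-to-signal ratio) pair the kernel Cholesky is
#' computed once and reused by all voxels, with the signal variance
#' maximized in closed form. Each voxel's grid optimum then seeds one
#' L-BFGS-B refinement of the full three-parameter marginal likelihood
#' (`refine = FALSE` skips it). Zero-variance voxels get a flat model.
#'
#' @param B t x v matrix of training amplitudes.
#' @param theta training directions in degrees (length t, >= 16).
#' @param grid prediction grid in degrees.
#' @param ell_bounds length-scale bounds (radian units).
#' @param n_ell,n_rho grid resolution over length-scale and
#'   noise-to-signal ratio.
#' @param refine run the per-voxel gradient refinement (default TRUE).
#' @return list of `fdtf` models, one per column of `B`.
#' @export
fit_fdtf_batch <- function(B, theta, grid = 1:360,
                           ell_bounds = c(0.05, 10),
                           n_ell = 20, n_rho = 16, refine = TRUE) {
  B <- as.matrix(B)
  n <- nrow(B); v <- ncol(B)
  stopifnot(length(theta) == n)
  if (n < 16) stop("need at least 16 training trials (got ", n, ")")
  D <- sin2_half(theta)
  centers <- colMeans(B)
  Yc <- sweep(B, 2, centers)
  vys <- apply(B, 2, stats::var)
  const <- 0.5 * n * (1 + log(2 * pi))

  ells <- exp(seq(log(ell_bounds[1]), log(ell_bounds[2]),
                  length.out = n_ell))
  rhos <- exp(seq(log(1e-3), log(1e3), length.out = n_rho))
  best_nlml <- rep(Inf, v)
  best_par <- matrix(NA_real_, v, 3)
  for (ell in ells) {
    C <- exp(-2 * D / ell^2)
    for (rho in rhos) {
      U <- tryCatch(chol(C + diag(rho + 1e-10, n)), error = function(e) NULL)
      if (is.null(U)) next
      Z <- backsolve(U, Yc, transpose = TRUE)
      q <- colSums(Z^2)
      sf2 <- pmax(q / n, 1e-12)
      nlml <- 0.5 * n * log(sf2) + sum(log(diag(U))) + const
      better <- which(nlml < best_nlml & is.finite(nlml))
      if (length(better)) {
        best_nlml[better] <- nlml[better]
        best_par[better, 1] <- ell
        best_par[better, 2] <- sf2[better]
        best_par[better, 3] <- rho * sf2[better]
      }
    }
  }

  lapply(seq_len(v), function(j) {
    vy <- vys[j]
    if (!is.finite(vy) || vy < 1e-12 || !is.finite(best_nlml[j]))
      return(flat_fdtf(centers[j], max(vy, 1e-12, na.rm = TRUE), theta,
                       grid, n))
    jitter <- 1e-10 * vy
    lower <- log(c(ell_bounds[1], 1e-6 * vy, 1e-6 * vy))
    upper <- log(c(ell_bounds[2], 10 * vy, 10 * vy))
    p0 <- pmin(pmax(log(best_par[j, ]), lower), upper)
    compute <- gp_objective(Yc[, j], D, jitter)
    p <- p0
    if (refine) {
      fit <- tryCatch(
        stats::optim(p0, fn = function(p) compute(p)$nlml,
                     gr = function(p) compute(p)$grad,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$value) && fit$value < 1e10)
        p <- fit$par
    }
    build_fdtf(p, compute, centers[j], theta, grid, n)
  })
}

# degenerate FDTF: constant mean, pure-noise variance
flat_fdtf <- function(center, sn2, theta, grid, n) {
  structure(list(ell = 1, sf2 = 0, sn2 = sn2, center = center,
                 theta_train = theta, alpha = NULL, U = NULL,
                 nlml = NA_real_, n_train = n, flat = TRUE, grid = grid,
                 grid_mean = rep(center, length(grid)),
                 grid_var = rep(sn2, length(grid))),
            class = "fdtf")
}

#' GP posterior predictive of an FDTF at arbitrary directions
#'
#' Standard GP posterior with the fitted periodic kernel. The predictive
#' variance includes the noise variance, so each direction's prediction is
#' the full direction-conditional response distribution (the "vertical
#' section" likelihood), not just the tuning-curve uncertainty.
#'
#' @param model an `fdtf` from [fit_voxel_gpr()].
#' @param grid directions in degrees.
#' @return list with `mean` and `var` (both `length(grid)`).
#' @export
predict_fdtf <- function(model, grid = model$grid) {
  if (isTRUE(model$flat))
    return(list(mean = rep(model$center, length(grid)),
                var = rep(model$sn2, length(grid))))
  ks <- cyclic_kernel(grid, model$theta_train, model$ell, model$sf2)
  mean <- model$center + as.numeric(ks %*% model$alpha)
  V <- backsolve(model$U, t(ks), transpose = TRUE)
  var_f <- pmax(model$sf2 - colSums(V^2), 0)
  list(mean = mean, var = var_f + model$sn2)
}

#' @export
print.fdtf <- function(x, ...) {
  cat(sprintf(
    "cyclic GP tuning function: ell = %.3f, sf2 = %.4g, sn2 = %.4g (n = %d%s)\n",
    x$ell, x$sf2, x$sn2, x$n_train, if (isTRUE(x$flat)) ", flat" else ""))
  invisible(x)
}
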