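#' Voxels within a searchlight sphere
#'
#' Members are all voxels whose Euclidean lattice distance from the center
#' voxel is at most `radius` (in voxel units); the sphere is clipped at
#' the volume borders simply because voxels outside the lattice do not
#' exist. An interior center with `radius = 4` on a full lattice has 257
#' members.
#'
#' @param coords integer matrix (voxels x 3) of lattice coordinates.
#' @param center index (row of `coords`) of the center voxel.
#' @param radius searchlight radius in voxel units.
#' @return integer vector of member row indices (center included).
#' @export
extract_searchlight <- function(coords, center, radius = 4) {
  coords <- as.matrix(coords)
  stopifnot(center >= 1, center <= nrow(coords))
  d2 <- colSums((t(coords) - coords[center, ])^2)
  which(d2 <= radius^2 + 1e-9)
}

#' Raw residual covariance of a searchlight's tuning models
#'
#' `Sigma = (1/t) * t(R) %*% R` where `R` is the trials x voxels matrix of
#' residuals of the training amplitudes around the GP predictive means at
#' the training directions, and `t` the number of training trials.
#'
#' @param B_train training amplitudes (t x v).
#' @param predictions GP predictive means at the training directions
#'   (t x v).
#' @return v x v covariance matrix (symmetric positive semidefinite).
#' @export
residual_covariance <- function(B_train, predictions) {
  B_train <- as.matrix(B_train); predictions <- as.matrix(predictions)
  stopifnot(all(dim(B_train) == dim(predictions)))
  t_n <- nrow(B_train)
  if (t_n == 0) stop("no training trials")
  R <- B_train - predictions
  crossprod(R) / t_n
}

#' Shrinkage mixing coefficient from the voxel-to-trial ratio
#'
#' How strongly the raw residual covariance is shrunk toward its diagonal,
#' as a function of `x = v / t` (voxels per training trial). Both maps are
#' strictly increasing with `r(1) = 1/2`, `r -> 0` as `x -> 0` and
#' `r -> 1` as `x -> Inf`:
#' \describe{
#'   \item{`logistic`}{`r = 1 / (1 + exp(-ln x)) = x / (1 + x)`.}
#'   \item{`arctan`}{`r = 1/2 + arctan(ln x) / pi`.}
#'   \item{`printed-arctan`}{`r = arctan(ln x) / pi`, the arctan form
#'     without the 1/2 offset. Provided for comparison only: it yields
#'     `r(1) = 0` and limits -1/2 and +1/2, so it cannot serve as a
#'     shrinkage weight.}
#' }
#'
#' @param v number of voxels (>= 1).
#' @param t number of training trials (>= 1).
#' @param method `"arctan"` (default), `"logistic"` or `"printed-arctan"`.
#' @return the mixing coefficient.
#' @export
mixing_coefficient <- function(v, t, method = c("arctan", "logistic",
                                                "printed-arctan")) {
  method <- match.arg(method)
  if (any(v <= 0) || any(t <= 0)) stop("v and t must be positive")
  x <- v / t
  switch(method,
    logistic = x / (1 + x),
    arctan = 0.5 + atan(log(x)) / pi,
    `printed-arctan` = atan(log(x)) / pi)
}

#' Shrink a covariance matrix toward its diagonal
#'
#' Convex combination of the raw covariance with the diagonal matrix of
#' its own sample variances: `(1 - r) * Sigma + r * diag(Sigma)`. The
#' diagonal is unchanged for any `r`; for `r > 0` and positive sample
#' variances the result is positive definite even when voxels outnumber
#' trials.
#'
#' @param Sigma symmetric covariance matrix.
#' @param r mixing coefficient in \[0, 1\].
#' @return the shrunk covariance.
#' @export
shrink_covariance <- function(Sigma, r) {
  stopifnot(r >= 0, r <= 1)
  Sigma <- as.matrix(Sigma)
  (1 - r) * Sigma + r * diag(diag(Sigma), nrow(Sigma))
}

#' Fit a searchlight reconstruction model on one training fold
#'
#' Fits an FDTF per member voxel on the training trials, caches the grid
#' of predictive means, and estimates the shrunk residual covariance (the
#' GP noise is carried by the residuals, so it enters the covariance
#' diagonal rather than being added twice).
#'
#' @param B_train t x v matrix of training amplitudes (searchlight members
#'   only).
#' @param theta_train training directions in degrees.
#' @param regularizer covariance mixing method, see
#'   [mixing_coefficient()].
#' @param grid decoding grid in degrees.
#' @param ... passed to [fit_fdtf_batch()] (grid resolution, refinement).
#' @return list (class `searchlight_model`) with `fdtfs`, `G` (grid x v
#'   predictive means), `Sigma` (shrunk), `U` (its Cholesky factor), `r`,
#'   `t_train`, `grid`.
#' @export
fit_searchlight_model <- function(B_train, theta_train,
                                  regularizer = "arctan", grid = 1:360,
                                  ...) {
  B_train <- as.matrix(B_train)
  t_n <- nrow(B_train); v <- ncol(B_train)
  stopifnot(length(theta_train) == t_n)
  fdtfs <- fit_fdtf_batch(B_train, theta_train, grid = grid, ...)
  G <- vapply(fdtfs, function(m) m$grid_mean, numeric(length(grid)))
  H <- vapply(fdtfs, function(m) predict_fdtf(m, theta_train)$mean,
              numeric(t_n))
  Sigma_raw <- residual_covariance(B_train, H)
  r <- mixing_coefficient(v, t_n, regularizer)
  Sigma <- shrink_covariance(Sigma_raw, r)
  U <- tryCatch(chol(Sigma), error = function(e)
    stop("shrunk covariance is not positive definite; ",
         "check for zero-variance voxels or increase shrinkage"))
  structure(list(fdtfs = fdtfs, G = G, Sigma = Sigma, U = U, r = r,
                 t_train = t_n, grid = grid),
            class = "searchlight_model")
}

#' Log-likelihood profile of one test trial over the direction grid
#'
#' The multivariate normal log density of the trial's amplitude vector at
#' each candidate direction's predicted mean pattern, with the fold's
#' shrunk residual covariance; evaluated through the cached Cholesky
#' factorization.
#'
#' @param beta_row numeric vector of the test trial's v amplitudes.
#' @param model a `searchlight_model`.
#' @return numeric vector of log-likelihood values over `model$grid`.
#' @export
loglik_profile <- function(beta_row, model) {
  v <- ncol(model$G)
  stopifnot(length(beta_row) == v)
  diffs <- t(model$G) - beta_row           # v x n_grid: g(theta) - beta
  W <- backsolve(model$U, diffs, transpose = TRUE)
  logdet <- 2 * sum(log(diag(model$U)))
  -0.5 * (colSums(W^2) + logdet + v * log(2 * pi))
}

#' Maximum-likelihood direction from a likelihood profile
#'
#' Argmax over the grid; ties are broken by the smallest angle (first grid
#' point). A decoded 360 degrees is reported as 0 for convention
#' consistency.
#'
#' @param profile numeric vector of (log-)likelihood values.
#' @param grid matching directions in degrees.
#' @return the decoded direction in degrees in \[0, 360).
#' @export
decode_trial <- function(profile, grid = seq_along(profile)) {
  if (any(!is.finite(profile))) stop("likelihood profile must be finite")
  wrap360(grid[which.max(profile)])
}

#' Run the searchlight reconstruction across folds
#'
#' For each leave-one-run-out fold of each requested condition
#' (coherence x label), fits the searchlight model on the training trials
#' and decodes every valid test trial by grid MLE. Labels are the stimulus
#' direction (`theta_s`) or the reported direction (`theta_r`).
#'
#' @param betas a `beta_matrix` covering all trials.
#' @param members voxel indices (columns of `betas$values`) forming the
#'   searchlight; see [extract_searchlight()].
#' @param coherences coherence labels to decode (default: all present).
#' @param labels label types to decode: `"stimulus"`, `"report"` or both.
#' @param regularizer covariance mixing method.
#' @param grid decoding grid in degrees.
#' @param ... passed to [fit_fdtf_batch()].
#' @return a `data.frame` with one row per decoded trial: `trial_id`,
#'   `run` (fold), `coherence`, `label_type`, `theta_true`, `theta_hat`.
#' @export
run_reconstruction <- function(betas, members = seq_len(ncol(betas$values)),
                               coherences = NULL,
                               labels = c("stimulus", "report"),
                               regularizer = "arctan", grid = 1:360,
                               ...) {
  trials <- betas$trials
  if (is.null(coherences)) coherences <- unique(trials$coherence)
  labels <- match.arg(labels, several.ok = TRUE)
  out <- list()
  for (coh in coherences) {
    sub <- trials[trials$coherence == coh, ]
    for (lab in labels) {
      lab_col <- if (lab == "stimulus") "theta_s" else "theta_r"
      sub_l <- sub
      sub_l$valid <- sub_l$valid & is.finite(sub_l[[lab_col]])
      folds <- make_cv_folds(sub_l)
      for (f in folds) {
        tr_rows <- match(f$train_ids, trials$trial_id)
        te_rows <- match(f$test_ids, trials$trial_id)
        model <- fit_searchlight_model(
          betas$values[tr_rows, members, drop = FALSE],
          trials[[lab_col]][tr_rows],
          regularizer = regularizer, grid = grid, ...)
        theta_hat <- vapply(te_rows, function(i) {
          decode_trial(loglik_profile(betas$values[i, members], model),
                       grid)
        }, numeric(1))
        out[[length(out) + 1]] <- data.frame(
          trial_id = f$test_ids, run = f$run, coherence = coh,
          label_type = lab, theta_true = trials[[lab_col]][te_rows],
          theta_hat = theta_hat, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
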