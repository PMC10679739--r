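#' Mean feature-continuous accuracy of reconstructions
#'
#' Mean over trials of `fca(circular_deviation(theta_true, theta_hat))`.
#'
#' @param theta_true,theta_hat aligned direction vectors in degrees.
#' @return mean FCA in percent.
#' @export
score_fca <- function(theta_true, theta_hat) {
  if (length(theta_true) != length(theta_hat))
    stop("theta_true and theta_hat must have the same length")
  mean(fca(circular_deviation(theta_true, theta_hat)))
}

#' Balanced feature-continuous accuracy (BFCA)
#'
#' FCA integrated over the true-direction axis: trials are sorted by
#' `theta_true` (per-trial FCA values at duplicated directions are
#' averaged first), the first sorted point is re-appended at
#' `theta + 360` to close the circle, and the trapezoid rule integral is
#' divided by 360. This weights each region of the direction space
#' equally, removing the spurious accuracy a constant decoder would earn
#' from an unbalanced label distribution. With balanced labels BFCA and
#' FCA are virtually identical.
#'
#' @param theta_true,theta_hat aligned direction vectors in degrees (at
#'   least 2 distinct true directions).
#' @param close_circle append the first sorted point at `theta + 360`
#'   before integrating (default TRUE); without it the integral does not
#'   cover the full circle.
#' @return BFCA in percent.
#' @export
score_bfca <- function(theta_true, theta_hat, close_circle = TRUE) {
  if (length(theta_true) != length(theta_hat))
    stop("theta_true and theta_hat must have the same length")
  if (length(theta_true) < 2)
    stop("need at least 2 trials")
  th <- wrap360(theta_true)
  acc <- fca(circular_deviation(theta_true, theta_hat))
  # average duplicates (zero-width trapezoids otherwise)
  agg <- tapply(acc, th, mean)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  if (length(x) < 2)
    stop("degenerate support: all true directions are identical")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  if (close_circle) {
    x <- c(x, x[1] + 360)
    y <- c(y, y[1])
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
    (if (close_circle) 360 else diff(range(x)))
}

#' Aggregate reconstruction results over ROIs and conditions
#'
#' Computes mean FCA and BFCA with trial counts per combination of voxel
#' group (e.g. ROI of the searchlight center), coherence and label type.
#'
#' @param results reconstruction results from [run_reconstruction()],
#'   optionally with a `group` column; if absent, `group` is taken from
#'   `voxel_groups[results$center]` or set to `"all"`.
#' @param voxel_groups optional named vector mapping searchlight centers
#'   to group labels.
#' @return a `data.frame` with `group`, `coherence`, `label_type`,
#'   `mean_fca`, `bfca`, `n_trials`, `chance`.
#' @export
aggregate_accuracy <- function(results, voxel_groups = NULL) {
  if (!"group" %in% names(results)) {
    results$group <- if (!is.null(voxel_groups) && "center" %in% names(results))
      voxel_groups[as.character(results$center)] else "all"
  }
  keys <- unique(results[c("group", "coherence", "label_type")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- results$group == keys$group[i] &
      results$coherence == keys$coherence[i] &
      results$label_type == keys$label_type[i]
    r <- results[sel, ]
    data.frame(keys[i, ],
               mean_fca = if (nrow(r)) score_fca(r$theta_true, r$theta_hat)
                          else NA_real_,
               bfca = if (nrow(r) >= 2) score_bfca(r$theta_true, r$theta_hat)
                      else NA_real_,
               n_trials = nrow(r), chance = 50, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cross-condition model generalization
#'
#' Trains the searchlight model in one condition (label x coherence) and
#' decodes the trials of another, respecting the leave-one-run-out
#' structure: the model trained on all runs but `r` of the model condition
#' decodes the held-out run `r` trials of the data condition. The headline
#' use is training on reports at zero coherence (pure guessing, no
#' stimulus contamination) and decoding the stimulus at full coherence: if
#' that generalizes, choices and stimuli share a representational format.
#'
#' @param betas a `beta_matrix`.
#' @param model_condition,data_condition lists with elements `label`
#'   (`"stimulus"` or `"report"`) and `coherence` (a coherence label).
#' @param members searchlight voxel indices.
#' @param regularizer,grid,... as in [run_reconstruction()].
#' @return list with `bfca`, `mean_fca`, `n_trials` and the per-trial
#'   `results` data.frame.
#' @export
cross_predict <- function(betas, model_condition, data_condition,
                          members = seq_len(ncol(betas$values)),
                          regularizer = "arctan", grid = 1:360, ...) {
  trials <- betas$trials
  pick <- function(cond) {
    col <- if (cond$label == "stimulus") "theta_s" else "theta_r"
    sub <- trials[trials$coherence == cond$coherence, ]
    sub$valid <- sub$valid & is.finite(sub[[col]])
    list(sub = sub, col = col)
  }
  mc <- pick(model_condition)
  dc <- pick(data_condition)
  if (nrow(mc$sub) == 0 || nrow(dc$sub) == 0)
    stop("no trials for the requested condition pair")
  runs <- intersect(unique(mc$sub$run), unique(dc$sub$run))
  if (length(runs) < 2)
    stop("conditions share fewer than 2 runs; fold structure impossible")
  out <- list()
  for (r in runs) {
    train <- mc$sub[mc$sub$valid & mc$sub$run != r, ]
    test <- dc$sub[dc$sub$valid & dc$sub$run == r, ]
    if (nrow(test) == 0) next
    tr_rows <- match(train$trial_id, trials$trial_id)
    te_rows <- match(test$trial_id, trials$trial_id)
    model <- fit_searchlight_model(
      betas$values[tr_rows, members, drop = FALSE],
      train[[mc$col]], regularizer = regularizer, grid = grid, ...)
    theta_hat <- vapply(te_rows, function(i) {
      decode_trial(loglik_profile(betas$values[i, members], model), grid)
    }, numeric(1))
    out[[length(out) + 1]] <- data.frame(
      trial_id = test$trial_id, run = r,
      theta_true = test[[dc$col]], theta_hat = theta_hat)
  }
  res <- do.call(rbind, out)
  list(bfca = score_bfca(res$theta_true, res$theta_hat),
       mean_fca = score_fca(res$theta_true, res$theta_hat),
       n_trials = nrow(res), results = res)
}

#' One-tailed t-test of accuracy above chance
#'
#' Plain one-sample t statistic of a set of accuracy values against the
#' chance level, with the upper-tail p-value.
#'
#' @param x accuracy values (e.g. per-subject BFCA).
#' @param chance chance level (default 50).
#' @return list with `t`, `df`, `p` (one-tailed) and `mean`.
#' @export
t_test_above_chance <- function(x, chance = 50) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 values")
  tt <- (mean(x) - chance) / (stats::sd(x) / sqrt(n))
  list(t = tt, df = n - 1, p = stats::pt(tt, n - 1, lower.tail = FALSE),
       mean = mean(x))
}
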