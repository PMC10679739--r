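#' Hidden randomization bin edges
#'
#' The direction space is divided into eight 45-degree bins used to
#' pseudo-randomize directions while keeping the task continuous. Bin 1 is
#' centered on 0 degrees (up), so its edges wrap around 360.
#'
#' @return numeric vector of the 8 lower bin edges in degrees.
#' @export
direction_bin_edges <- function() {
  c(337.5, 22.5, 67.5, 112.5, 157.5, 202.5, 247.5, 292.5)
}

#' Bin index of a direction
#'
#' @param theta directions in degrees.
#' @return integer bin index in 1..8 (bin 1 spans 337.5..22.5 across 0).
#' @export
direction_bin <- function(theta) {
  as.integer(floor(wrap360(theta + 22.5) / 45)) + 1L
}

# Draw a direction uniformly inside a bin (bin centers at (b-1)*45 deg).
runif_in_bin <- function(bin) {
  center <- (bin - 1L) * 45
  wrap360(center + stats::runif(length(bin), -22.5, 22.5))
}

# Sample one ITI per trial from {3,5,7,9} s with geometrically decaying
# probability (decay 0.5), so shorter intervals are more frequent.
sample_itis <- function(n, choices = c(3, 5, 7, 9), decay = 0.5) {
  p <- decay^(seq_along(choices) - 1)
  sample(choices, n, replace = TRUE, prob = p / sum(p))
}

# Order a multiset of (coherence, bin) tokens such that the same bin never
# occurs more than twice in a row and the same coherence never more than
# three times in a row. Sequential sampling with restart on dead ends.
# With a single coherence level the coherence constraint is vacuous (it
# could never be satisfied) and only the bin constraint applies.
sequence_tokens <- function(tokens, max_attempts = 500) {
  n <- nrow(tokens)
  multi_coh <- length(unique(tokens$coherence)) > 1
  for (attempt in seq_len(max_attempts)) {
    remaining <- seq_len(n)
    order_idx <- integer(n)
    ok <- TRUE
    last_bins <- c(NA_integer_, NA_integer_)
    last_cohs <- c(NA_character_, NA_character_, NA_character_)
    for (pos in seq_len(n)) {
      cand <- remaining
      if (!anyNA(last_bins) && last_bins[1] == last_bins[2])
        cand <- cand[tokens$bin[cand] != last_bins[1]]
      if (multi_coh && !anyNA(last_cohs) && last_cohs[1] == last_cohs[2] &&
          last_cohs[2] == last_cohs[3])
        cand <- cand[tokens$coherence[cand] != last_cohs[1]]
      if (length(cand) == 0) { ok <- FALSE; break }
      pick <- if (length(cand) == 1) cand else sample(cand, 1)
      order_idx[pos] <- pick
      remaining <- setdiff(remaining, pick)
      last_bins <- c(tokens$bin[pick], last_bins[1])
      last_cohs <- c(tokens$coherence[pick], last_cohs[1:2])
    }
    if (ok) return(order_idx)
  }
  stop("could not order trials under the bin/coherence run-length ",
       "constraints after ", max_attempts, " attempts")
}

#' Generate a pseudo-randomized trial sequence
#'
#' Builds the session design of a continuous motion-direction experiment:
#' `n_runs` runs, each presenting every coherence level
#' `trials_per_coherence` times. Directions are drawn uniformly within
#' eight hidden 45-degree randomization bins whose counts are balanced
#' within each coherence across the session; the same bin never occurs
#' more than twice in a row and the same coherence never more than three
#' times in a row. Each trial lasts 0.5 s fixation + 2 s stimulus + 7.5 s
#' report, followed by an ITI drawn from 3/5/7/9 s with geometrically
#' decreasing frequency.
#'
#' At zero coherence the stimulus carries no net motion; `theta_s` is
#' still assigned by the same randomization scheme but is a label only and
#' has no generative effect on voxel responses (see [simulate_betas()]).
#'
#' @param n_runs number of runs.
#' @param trials_per_coherence trials per coherence level per run.
#' @param coherence_levels named numeric vector of motion coherences in
#'   \[0, 1\]; names are the condition labels. The default follows the
#'   scanned design: zero, intermediate and full coherence.
#' @param seed integer seed; all randomness is drawn from it.
#' @return a `data.frame` (class `trial_table`) with columns `trial_id`,
#'   `run`, `coherence`, `coherence_level`, `theta_s`, `theta_r` (NA until
#'   reports are simulated), `theta_gen` (NA; generative direction set by
#'   [simulate_reports()]), `bin_index`, `onset` (stimulus onset, s),
#'   `iti` (s) and `valid`.
#' @export
#' @examples
#' tt <- generate_trial_sequence(2, 16, seed = 1)
#' table(tt$run, tt$coherence)
generate_trial_sequence <- function(n_runs = 10,
                                    trials_per_coherence = 16,
                                    coherence_levels = c(zero = 0,
                                                         intermediate = 0.2,
                                                         full = 1),
                                    seed = 1) {
  n_bins <- 8L
  if (n_runs < 1 || trials_per_coherence < 1)
    stop("configuration error: n_runs and trials_per_coherence must be >= 1")
  if (is.null(names(coherence_levels)) || anyDuplicated(names(coherence_levels)))
    stop("configuration error: coherence_levels must have unique names")
  total_per_coh <- n_runs * trials_per_coherence
  if (total_per_coh %% n_bins != 0)
    stop("configuration error: n_runs * trials_per_coherence (",
         total_per_coh, ") must be divisible by the ", n_bins,
         " randomization bins")
  set.seed(as.integer(seed))

  # Session-level balanced bin allocation per coherence, chunked into runs.
  coh_labels <- names(coherence_levels)
  bins_by_run <- lapply(coh_labels, function(lbl) {
    bins <- sample(rep(seq_len(n_bins), total_per_coh / n_bins))
    split(bins, rep(seq_len(n_runs), each = trials_per_coherence))
  })
  names(bins_by_run) <- coh_labels

  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    tokens <- do.call(rbind, lapply(coh_labels, function(lbl) {
      data.frame(coherence = lbl, bin = bins_by_run[[lbl]][[r]],
                 stringsAsFactors = FALSE)
    }))
    ord <- sequence_tokens(tokens)
    tokens <- tokens[ord, , drop = FALSE]
    n_tr <- nrow(tokens)
    itis <- sample_itis(n_tr)
    trial_len <- 0.5 + 2 + 7.5
    starts <- cumsum(c(0, (trial_len + itis)[-n_tr]))
    rows[[r]] <- data.frame(
      run = r,
      coherence = tokens$coherence,
      coherence_level = unname(coherence_levels[tokens$coherence]),
      theta_s = runif_in_bin(tokens$bin),
      theta_r = NA_real_,
      theta_gen = NA_real_,
      bin_index = tokens$bin,
      onset = starts + 0.5,
      iti = itis,
      valid = TRUE,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- cbind(trial_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Write / read a trial table as a BIDS-style events TSV
#'
#' Columns follow the events-file convention (`onset`, `duration`, then
#' design and behavior columns). `duration` is the 2 s stimulus period.
#'
#' @param trials a trial table.
#' @param path output TSV path.
#' @return `path`, invisibly (writer); a `trial_table` (reader).
#' @export
write_trial_table <- function(trials, path) {
  df <- as.data.frame(trials)
  df$duration <- 2
  cols <- c("onset", "duration", "trial_id", "run", "coherence",
            "coherence_level", "theta_s", "theta_r", "theta_gen",
            "bin_index", "iti", "valid")
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  df$duration <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}
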