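#' Simulate gaze traces for the stimulation periods
#'
#' Generates eye-position samples at a fixed rate covering each trial's
#' 2 s stimulation window. Baseline gaze jitters around fixation as
#' independent Gaussian noise per axis; fixation breaks are injected as
#' position offsets of given onset, duration and amplitude within a
#' trial's stimulation period. Blinks can be injected as invalid samples
#' that carry no position.
#'
#' @param trials a trial table (onsets are the stimulus onsets).
#' @param fixation_sd baseline jitter SD per axis, in degrees of visual
#'   angle (dva).
#' @param excursions `NULL` or a `data.frame` with columns `trial_id`,
#'   `onset` (s, relative to stimulus onset), `duration` (s) and
#'   `amplitude` (dva); each is added to the x coordinate for its span.
#' @param blinks like `excursions` but columns `trial_id`, `onset`,
#'   `duration`: samples in the span are marked invalid with no position.
#' @param sampling_rate samples per second (default 1000 Hz).
#' @param seed integer seed.
#' @return a `data.frame` (class `gaze_record`) with columns `time`
#'   (absolute seconds), `x`, `y` (dva; `NA` when invalid),
#'   `valid_sample`, `run`, `trial_id`.
#' @export
simulate_gaze <- function(trials, fixation_sd = 0.1, excursions = NULL,
                          blinks = NULL, sampling_rate = 1000, seed = 1) {
  set.seed(as.integer(seed))
  dt <- 1 / sampling_rate
  window <- 2
  check_span <- function(df, what) {
    if (is.null(df)) return(invisible())
    bad <- df$onset < 0 | df$onset + df$duration > window
    if (any(bad))
      stop(what, " outside the stimulation window for trial(s): ",
           paste(df$trial_id[bad], collapse = ", "))
  }
  check_span(excursions, "excursion")
  check_span(blinks, "blink")

  per_trial <- lapply(seq_len(nrow(trials)), function(i) {
    rel_t <- seq(0, window - dt, by = dt)
    n <- length(rel_t)
    x <- stats::rnorm(n, 0, fixation_sd)
    y <- stats::rnorm(n, 0, fixation_sd)
    valid <- rep(TRUE, n)
    id <- trials$trial_id[i]
    if (!is.null(excursions)) {
      ex <- excursions[excursions$trial_id == id, , drop = FALSE]
      for (k in seq_len(nrow(ex))) {
        span <- rel_t >= ex$onset[k] & rel_t < ex$onset[k] + ex$duration[k]
        x[span] <- x[span] + ex$amplitude[k]
      }
    }
    if (!is.null(blinks)) {
      bl <- blinks[blinks$trial_id == id, , drop = FALSE]
      for (k in seq_len(nrow(bl))) {
        span <- rel_t >= bl$onset[k] & rel_t < bl$onset[k] + bl$duration[k]
        valid[span] <- FALSE
      }
    }
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    data.frame(time = trials$onset[i] + rel_t, x = x, y = y,
               valid_sample = valid, run = trials$run[i], trial_id = id)
  })
  out <- do.call(rbind, per_trial)
  rownames(out) <- NULL
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("gaze_record", "data.frame")
  out
}

#' Write / read gaze records as TSV
#'
#' @param gaze a `gaze_record`.
#' @param path output TSV path.
#' @param sampling_rate sampling rate to attach when reading.
#' @return `path` invisibly (writer); a `gaze_record` (reader).
#' @export
write_gaze_record <- function(gaze, path) {
  utils::write.table(as.data.frame(gaze), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_gaze_record
#' @export
read_gaze_record <- function(path, sampling_rate = 1000) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                          stringsAsFactors = FALSE)
  attr(df, "sampling_rate") <- sampling_rate
  class(df) <- c("gaze_record", "data.frame")
  df
}
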