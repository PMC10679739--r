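#' Generate a population of direction-tuned voxels on an integer lattice
#'
#' Each voxel has a smooth cyclic tuning profile — a rescaled von Mises
#' bump, optionally mixed with a second harmonic — of heterogeneous
#' amplitude, width and preferred direction, plus a baseline and a
#' Gaussian trial-noise scale. A configurable fraction of voxels is
#' informative; the rest are flat (amplitude 0). Voxel coordinates are
#' unique integer lattice positions.
#'
#' @param n_voxels number of voxels (must fit on the lattice).
#' @param grid_shape integer 3-vector of lattice extents.
#' @param tuning_spec list with elements `informative_fraction` (in
#'   \[0,1\]), `amplitude_range`, `width_range` (von Mises concentration of
#'   the bump), `baseline_range`, `noise_sd_range` (all length-2 numeric
#'   ranges), and `second_harmonic_max` (max weight of a 180-degree
#'   periodic component, 0 disables it).
#' @param roi_label ROI label assigned to all voxels (a vector of length
#'   `n_voxels` is also accepted).
#' @param seed integer seed.
#' @return a `data.frame` (class `voxel_population`) with columns `voxel`,
#'   `x`, `y`, `z`, `roi_label`, `tuning_amplitude`, `tuning_width`,
#'   `tuning_phase`, `second_harmonic`, `baseline`, `noise_sd`,
#'   `informative`.
#' @export
generate_voxel_population <- function(n_voxels,
                                      grid_shape = c(8, 8, 8),
                                      tuning_spec = list(),
                                      roi_label = "ROI",
                                      seed = 1) {
  spec <- utils::modifyList(list(
    informative_fraction = 1,
    amplitude_range = c(0.5, 2),
    width_range = c(1, 4),
    baseline_range = c(-0.5, 0.5),
    noise_sd_range = c(0.2, 0.6),
    second_harmonic_max = 0
  ), tuning_spec)
  capacity <- prod(grid_shape)
  if (n_voxels > capacity)
    stop("n_voxels (", n_voxels, ") exceeds lattice capacity (", capacity, ")")
  set.seed(as.integer(seed))
  idx <- sample.int(capacity, n_voxels)
  coords <- arrayInd(idx, .dim = grid_shape)
  informative <- stats::runif(n_voxels) < spec$informative_fraction
  amp <- stats::runif(n_voxels, spec$amplitude_range[1], spec$amplitude_range[2])
  amp[!informative] <- 0
  out <- data.frame(
    voxel = seq_len(n_voxels),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    roi_label = rep_len(roi_label, n_voxels),
    tuning_amplitude = amp,
    tuning_width = stats::runif(n_voxels, spec$width_range[1],
                                spec$width_range[2]),
    # phases spread over the circle: stratified uniform so even small
    # populations tile the direction space
    tuning_phase = wrap360((seq_len(n_voxels) - 1) / n_voxels * 360 +
                           stats::runif(n_voxels, 0, 360 / n_voxels)),
    second_harmonic = stats::runif(n_voxels, 0, spec$second_harmonic_max),
    baseline = stats::runif(n_voxels, spec$baseline_range[1],
                            spec$baseline_range[2]),
    noise_sd = stats::runif(n_voxels, spec$noise_sd_range[1],
                            spec$noise_sd_range[2]),
    informative = informative,
    stringsAsFactors = FALSE
  )
  attr(out, "grid_shape") <- as.integer(grid_shape)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("voxel_population", "data.frame")
  out
}

#' Noise-free tuning profile of simulated voxels
#'
#' Evaluates each voxel's deterministic response (baseline + amplitude x
#' cyclic bump) at the given directions. The bump is a von Mises profile
#' `exp(width * (cos(theta - phase) - 1))` in \[0, 1\], optionally mixed
#' with a 180-degree periodic second harmonic.
#'
#' @param voxels a `voxel_population`.
#' @param theta directions in degrees.
#' @return a `length(theta)` x `n_voxels` matrix of mean responses.
#' @export
voxel_tuning <- function(voxels, theta) {
  d <- deg2rad(outer(theta, voxels$tuning_phase, "-"))
  bump <- exp(sweep(cos(d) - 1, 2, voxels$tuning_width, "*"))
  h2w <- voxels$second_harmonic
  if (any(h2w > 0)) {
    bump2 <- exp(sweep(cos(2 * d) - 1, 2, voxels$tuning_width, "*"))
    bump <- sweep(bump, 2, 1 - h2w, "*") + sweep(bump2, 2, h2w, "*")
  }
  sweep(sweep(bump, 2, voxels$tuning_amplitude, "*"),
        2, voxels$baseline, "+")
}

#' Simulate trial-wise response amplitudes
#'
#' Generates the trials x voxels amplitude matrix: each entry is the
#' voxel's tuning profile evaluated at the trial's generative direction
#' plus independent Gaussian noise with the voxel's noise SD. The
#' generative direction is `theta_gen` (stimulus direction at nonzero
#' coherence; at zero coherence the report latent — see
#' [simulate_reports()]).
#'
#' @param trials a trial table with `theta_gen` filled in.
#' @param voxels a `voxel_population`.
#' @param seed integer seed.
#' @return a `beta_matrix`: list with `values` (trials x voxels matrix),
#'   `trials` and `voxels`.
#' @export
simulate_betas <- function(trials, voxels, seed = 1) {
  if (nrow(trials) == 0 || nrow(voxels) == 0)
    stop("trials and voxels must be nonempty")
  if (any(is.na(trials$theta_gen)))
    stop("trials$theta_gen is missing; run simulate_reports() first")
  set.seed(as.integer(seed))
  mu <- voxel_tuning(voxels, trials$theta_gen)
  noise <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
  noise <- sweep(noise, 2, voxels$noise_sd, "*")
  beta_matrix(mu + noise, trials, voxels)
}

#' Trials x voxels amplitude container
#'
#' @param values numeric trials x voxels matrix of amplitude estimates.
#' @param trials the aligned trial table (rows match `values` rows).
#' @param voxels voxel metadata (rows match `values` columns).
#' @return an object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, trials, voxels) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(trials), ncol(values) == nrow(voxels),
            all(is.finite(values)))
  structure(list(values = values, trials = trials, voxels = voxels),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "trials x", ncol(x$values), "voxels\n")
  invisible(x)
}

#' Write / read a beta matrix as delimited text plus a JSON sidecar
#'
#' The amplitude matrix goes to a TSV; voxel coordinates/labels and the
#' trial table go to a JSON sidecar next to it.
#'
#' @param betas a `beta_matrix`.
#' @param path output TSV path (sidecar written as `<path>.json`).
#' @return `path`, invisibly (writer); a `beta_matrix` (reader).
#' @export
write_beta_matrix <- function(betas, path) {
  utils::write.table(betas$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- list(trials = as.data.frame(betas$trials),
               voxels = as.data.frame(betas$voxels))
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_beta_matrix
#' @export
read_beta_matrix <- function(path) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  trials <- side$trials
  class(trials) <- c("trial_table", "data.frame")
  beta_matrix(values, trials, side$voxels)
}
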