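#' Default pipeline configuration
#'
#' A small but complete end-to-end demonstration configuration: the full
#' session design (10 runs, 16 trials per coherence per run), a compact
#' informative voxel cluster, behavioral screening, fixation QC on
#' simulated gaze, within-condition reconstruction and the zero-coherence
#' report to full-coherence stimulus generalization.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return a configuration list for [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = as.integer(seed),
    design = list(n_runs = 10, trials_per_coherence = 16,
                  coherence_levels = c(zero = 0, intermediate = 0.2,
                                       full = 1)),
    mixture = default_report_mixture(),
    zero_latent = "report",
    voxels = list(n_voxels = 60, grid_shape = c(6, 6, 6),
                  tuning_spec = list(informative_fraction = 0.8,
                                     noise_sd_range = c(0.2, 0.4))),
    gaze = list(enabled = TRUE, fixation_sd = 0.15, sampling_rate = 250),
    decode = list(coherences = c("full", "zero"),
                  labels = c("stimulus", "report"),
                  regularizer = "arctan"),
    cross = list(list(model = list(label = "report", coherence = "zero"),
                      data = list(label = "stimulus", coherence = "full")))
  )
}

# derive a deterministic 32-bit sub-seed for a named pipeline stage
stage_seed <- function(seed, stage) {
  offsets <- c(design = 101, reports = 211, voxels = 307, betas = 401,
               gaze = 503, decode = 601)
  (as.integer(seed) * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> fixation QC -> behavior -> encoding +
#' searchlight reconstruction -> evaluation -> cross-prediction, and
#' writes each stage's outputs plus a manifest (with the config hash and
#' all stage seeds) under `out_dir`. Identical config and seed give
#' identical outputs.
#'
#' @param config a configuration list, see [default_pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return list with `trials`, `betas`, `qc`, `screening`, `results`
#'   (per-trial reconstructions), `summary` (accuracy table), `cross`
#'   (generalization results) and `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL) {
  seed <- config$seed
  trials <- do.call(generate_trial_sequence,
                    c(config$design, list(seed = stage_seed(seed, "design"))))
  trials <- simulate_reports(trials, config$mixture,
                             zero_latent = config$zero_latent,
                             seed = stage_seed(seed, "reports"))
  voxels <- do.call(generate_voxel_population,
                    c(config$voxels, list(seed = stage_seed(seed, "voxels"))))
  betas <- simulate_betas(trials, voxels, seed = stage_seed(seed, "betas"))

  qc <- NULL
  if (isTRUE(config$gaze$enabled)) {
    gaze <- simulate_gaze(trials, fixation_sd = config$gaze$fixation_sd,
                          sampling_rate = config$gaze$sampling_rate,
                          seed = stage_seed(seed, "gaze"))
    # threshold distribution widened with the session's own runs only;
    # a multi-subject reference can be passed through config$gaze$reference
    qc <- apply_fixation_qc(gaze, trials,
                            reference_sds = config$gaze$reference)
    trials$valid <- trials$valid & qc$valid
    betas$trials$valid <- trials$valid
  }

  full <- trials[trials$coherence == "full" & trials$valid, ]
  screening <- screen_participant(full)

  results <- run_reconstruction(
    betas,
    coherences = config$decode$coherences,
    labels = config$decode$labels,
    regularizer = config$decode$regularizer)
  summary <- aggregate_accuracy(results)

  cross <- lapply(config$cross, function(cp) {
    cr <- cross_predict(betas, cp$model, cp$data,
                        regularizer = config$decode$regularizer)
    c(list(model = cp$model, data = cp$data),
      cr[c("bfca", "mean_fca", "n_trials")])
  })

  manifest <- list(
    config_hash = hash_config(config),
    seed = seed,
    stage_seeds = sapply(c("design", "reports", "voxels", "betas", "gaze",
                           "decode"), function(s) stage_seed(seed, s)),
    n_trials = nrow(trials), n_voxels = nrow(voxels),
    n_valid = sum(trials$valid),
    n_model_sets = length(config$decode$coherences) *
      length(config$decode$labels))

  out <- list(trials = trials, voxels = voxels, betas = betas, qc = qc,
              screening = screening, results = results, summary = summary,
              cross = cross, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(trials, file.path(out_dir, "events.tsv"))
    write_beta_matrix(betas, file.path(out_dir, "betas.tsv"))
    utils::write.csv(results, file.path(out_dir, "reconstruction.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "accuracy_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(manifest = manifest,
           screening = screening[c("p95_deviation", "rood_rate", "include",
                                   "reasons")],
           cross = cross),
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

# md5 of the canonical JSON serialization of a config
hash_config <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       na = "null")
  unname(tools::md5sum(tmp))
}
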