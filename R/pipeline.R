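#' Pipeline configuration
#'
#' One declarative configuration for the whole pipeline.  The `"full"`
#' preset carries the full published-study scale (96 stimuli = 32
#' speakers x 3 vowels, 40 repetitions, 6 blocks, 1 kHz epochs, 5
#' splits, 50 permutations, 10,000 inference iterations, thresholds
#' 1.64/1.96, 0.1-30 Hz band-pass, 150 uV rejection).  The `"desk"`
#' preset is the reduced scale used for routine testing: 16 stimuli (8
#' speakers x 2 vowels), 20 repetitions, 8 participants, a 10-ms time
#' grid, 5 subaveraging permutations and 1,000 inference iterations.
#' Synthetic epochs are generated band-limited and artifact-free, so
#' the desk preset skips the preprocessing stage by default;
#' preprocessing is exercised by its own unit tests and enabled in the
#' full preset.
#'
#' @param preset "desk" or "full"
#' @param ... named overrides of top-level config entries (lists are
#'   merged)
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    seed = 1L,
    scale = list(n_speakers = 8, vowels = c("a", "u"), n_repetitions = 20,
                 vigilance_stimuli = 0, vigilance_repetitions = 0,
                 n_blocks = 4, n_participants = 8, n_raters = 20,
                 sfreq = 100, n_channels = 32),
    latent = list(n_latent = 2, loading_spec = NULL, uniqueness = 0.4),
    ratings = list(rater_noise_sd = 1.5, stimulus_jitter_sd = 0.3),
    acoustics = list(latent_mixing = 0, n_acoustic_dims = 2),
    truth = list(effect_windows = rbind(c(300, 500), c(100, 300)),
                 snr = 1, acoustic_gain = 1, taper = 0.5,
                 acoustic_windows = NULL, pattern_seed = 42),
    preprocess = list(enabled = FALSE),
    decoding = list(n_splits = 5, n_permutations = 5, svm_cost = 1,
                    shrinkage_mode = "auto"),
    inference = list(z_threshold_one_sided = 1.64,
                     z_threshold_two_sided = 1.96,
                     n_iterations = 1000, alpha = 0.05),
    models = c("M1", "M2", "M3"),
    min_icc = 0.5
  )
  if (preset == "full") {
    base$scale <- list(n_speakers = 32, vowels = c("a", "i", "u"),
                       n_repetitions = 40, vigilance_stimuli = 24,
                       vigilance_repetitions = 16, n_blocks = 6,
                       n_participants = 32, n_raters = 30,
                       sfreq = 1000, n_channels = 32)
    base$decoding$n_permutations <- 50
    base$inference$n_iterations <- 10000
    base$preprocess <- list(enabled = TRUE, bad_channel_sd = 4,
                            peak_to_peak_uv = 150, low_hz = 0.1,
                            high_hz = 30, filter_order = 4,
                            baseline_ms = c(-100, 0),
                            reference_labels = c("TP9", "TP10"))
  }
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]]))
      base[[nm]] <- utils::modifyList(base[[nm]], overrides[[nm]])
    else base[[nm]] <- overrides[[nm]]
  }
  structure(base, class = "pipeline_config")
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate -> (preprocess) -> neural RDM -> behavior ->
#' acoustics -> RSA -> inference, entirely in memory, and optionally
#' writes per-stage outputs plus a manifest to `out_dir`.
#'
#' @param config a `pipeline_config`
#' @param out_dir optional output directory
#' @return list with `design`, `space`, `ratings`, `acoustics`,
#'   `truth`, `neural` (list of `neural_rdm_series`), `behavior`
#'   (screen/means/correlations/pca/rdms), `acoustic_rdms`,
#'   `timecourses` (long data.frame), `inference` (nested list
#'   characteristic -> model -> `cluster_result`), `config`
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$scale
  stage_seed <- function(i) derive_seed(config$seed, i)

  # --- simulate -------------------------------------------------------
  stimuli <- make_stimulus_set(sc$n_speakers, sc$vowels)
  design <- generate_design(stimuli, sc$n_repetitions,
                            sc$vigilance_stimuli,
                            sc$vigilance_repetitions, sc$n_blocks,
                            seed = stage_seed(1))
  space <- generate_latent_space(sc$n_speakers, config$latent$n_latent,
                                 config$latent$loading_spec,
                                 config$latent$uniqueness,
                                 seed = stage_seed(2))
  ratings <- generate_ratings(space, stimuli, sc$n_raters,
                              rater_noise_sd = config$ratings$rater_noise_sd,
                              stimulus_jitter_sd =
                                config$ratings$stimulus_jitter_sd,
                              seed = stage_seed(3))
  ac <- do.call(generate_acoustics,
                c(list(space = space, stimuli = stimuli,
                       seed = stage_seed(4)), config$acoustics))
  acoustic_rdms <- acoustic_pca_rdms(ac$features, ac$ltas)
  # EEG acoustic-confound driver: either the latent acoustic dimensions
  # or the leading principal components of the measure table (the
  # confound then coincides with the geometry the acoustic covariate
  # RDMs describe)
  drv <- config$truth$acoustic_driver %||% "pca"
  eeg_acoustic_scores <- switch(drv,
    pca = {
      # map each latent acoustic dimension to the component that tracks
      # it best, so window k is driven by the PC geometry matching dim k
      sc_pc <- acoustic_rdms$pca$component_scores
      pick <- apply(abs(cor(ac$acoustic_scores, sc_pc)), 1, which.max)
      out <- sc_pc[, pick, drop = FALSE]
      rownames(out) <- rownames(sc_pc)
      out
    },
    latent = ac$acoustic_scores,
    stop("unknown acoustic_driver: ", drv))
  mont <- standard_montage()
  n_ch <- sc$n_channels
  patt <- random_scalp_patterns(config$latent$n_latent +
                                  config$acoustics$n_acoustic_dims,
                                as.matrix(mont[, c("x", "y", "z")]),
                                seed = config$truth$pattern_seed)
  if (n_ch < nrow(mont)) {
    keep <- unique(c(head(mont$label, n_ch - 2), "TP9", "TP10"))
    patt <- patt[, match(keep, mont$label), drop = FALSE]
  }
  nl <- config$latent$n_latent
  truth <- synthetic_truth(
    effect_windows = config$truth$effect_windows,
    scalp_patterns = patt[seq_len(nl), , drop = FALSE],
    acoustic_patterns = if (!is.null(config$truth$acoustic_windows))
      patt[nl + seq_len(nrow(config$truth$acoustic_windows)), ,
           drop = FALSE] else NULL,
    acoustic_windows = config$truth$acoustic_windows,
    snr = config$truth$snr,
    acoustic_gain = config$truth$acoustic_gain %||% 1,
    taper = config$truth$taper %||% 0.5, seed = config$seed)

  # --- per-participant EEG, preprocessing, neural RDM -----------------
  neural <- vector("list", sc$n_participants)
  for (p in seq_len(sc$n_participants)) {
    pid <- sprintf("P%02d", p)
    epochs <- generate_eeg(design, space, truth, n_channels = n_ch,
                           sfreq = sc$sfreq,
                           seed = stage_seed(100 + p),
                           acoustic_scores = eeg_acoustic_scores)
    if (isTRUE(config$preprocess$enabled))
      epochs <- preprocess_epochs(epochs, config$preprocess)
    dcfg <- do.call(decoding_config,
                    c(config$decoding, list(seed = stage_seed(200 + p))))
    neural[[p]] <- build_rdm_series(epochs, dcfg, participant_id = pid)
    if (!is.null(out_dir))
      write_rdm_archive(neural[[p]]$values, neural[[p]]$stimulus_ids,
                        "decoding_accuracy",
                        file.path(out_dir, paste0("rdm_", pid, ".rds")),
                        times = neural[[p]]$times, config = dcfg)
  }

  # --- behavior -------------------------------------------------------
  screen <- screen_raters(ratings)
  means <- mean_ratings(ratings, screen, min_icc = config$min_icc)
  correlations <- characteristic_correlations(means)
  pca <- pca_oblimin(means$values)
  retained <- colnames(means$values)
  beh_rdms <- lapply(setNames(retained, retained), function(ch)
    rating_rdm(means, ch)$values)

  # --- RSA ------------------------------------------------------------
  timecourses <- run_all_models(neural, beh_rdms, acoustic_rdms,
                                models = config$models)

  # --- inference ------------------------------------------------------
  icfg <- do.call(inference_config,
                  c(config$inference, list(seed = stage_seed(300))))
  inference <- lapply(setNames(retained, retained), function(ch) {
    lapply(setNames(config$models, config$models), function(mid) {
      m <- timecourse_matrix(timecourses, ch, mid)
      cluster_onesample(m, icfg, times = attr(m, "times"))
    })
  })

  res <- list(design = design, space = space, ratings = ratings,
              acoustics = ac, truth = truth, neural = neural,
              behavior = list(screen = screen, means = means,
                              correlations = correlations, pca = pca,
                              rdms = beh_rdms),
              acoustic_rdms = acoustic_rdms,
              timecourses = timecourses, inference = inference,
              config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# Write per-stage outputs plus a manifest with file hashes.
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_ratings_csv(res$ratings, file.path(out_dir, "ratings.csv"))
  write.csv(as.data.frame(res$acoustics$features),
            file.path(out_dir, "acoustic_features.csv"),
            row.names = FALSE)
  write.csv(data.frame(stimulus_id = rownames(res$behavior$means$values),
                       res$behavior$means$values, check.names = FALSE),
            file.path(out_dir, "mean_ratings.csv"), row.names = FALSE)
  write.csv(res$behavior$correlations,
            file.path(out_dir, "characteristic_correlations.csv"))
  write_timecourses_csv(res$timecourses,
                        file.path(out_dir, "timecourses.csv"))
  # results table in the style of a cluster-window summary
  rows <- list()
  for (ch in names(res$inference)) for (mid in names(res$inference[[ch]])) {
    cr <- res$inference[[ch]][[mid]]
    sig <- cr$significant
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = ch, model = mid,
      n_significant_clusters = nrow(sig),
      cluster_windows = if (nrow(sig))
        paste(sprintf("%g-%g", sig$start_ms, sig$end_ms),
              collapse = "; ") else "",
      peak_time_ms = cr$peak_time_ms, stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  write.csv(results, file.path(out_dir, "cluster_results.csv"),
            row.names = FALSE)
  cfg <- res$config
  cfg$latent$loading_spec <- NULL  # matrices echoed separately
  manifest <- list(
    package_version = as.character(utils::packageVersion("voicersa")),
    seed = res$config$seed, preset = res$config$preset,
    config = rapply(unclass(cfg), function(x) x, how = "replace"),
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(out_dir)
}
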