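#' Generate synthetic acoustic measures and long-term average spectra
#'
#' Emulates the acoustic characterization of short vowel recordings:
#' a table of 13 perceptually salient measures per stimulus (F0, the
#' first four formants, formant dispersion, harmonic-source spectral
#' shape, cepstral peak prominence, energy, harmonics-to-noise ratio)
#' and a long-term average spectrum (LTAS) per stimulus.
#'
#' The 13 measures are driven by a small number of latent acoustic
#' dimensions.  Acoustic dimension k is a standardized mix of speaker
#' latent traits (via `latent_mixing`, n_latent x n_acoustic_dims),
#' speaker gender, vowel identity and independent noise, so the degree
#' of acoustic confounding with the person characteristics is fully
#' controlled: `latent_mixing = 0` makes acoustics independent of the
#' latent trait space.
#'
#' @param space a `latent_person_space`
#' @param stimuli stimulus set
#' @param seed integer seed
#' @param latent_mixing numeric matrix n_latent x n_acoustic_dims of
#'   weights from latent traits into acoustic dimensions (0 = no
#'   acoustic confound).  Default 0.
#' @param n_acoustic_dims number of latent acoustic dimensions
#' @param gender_weight,vowel_weight,noise_weight contributions of
#'   speaker gender, vowel and stimulus noise to the acoustic
#'   dimensions
#' @param bin_hz,fmax LTAS bin width and maximum frequency (Hz)
#' @return list with `features` (class `acoustic_features`: data.frame,
#'   13 measure columns + `stimulus_id`), `ltas` (class `ltas_matrix`:
#'   list with `spectra` stimulus x bin linear power, `bin_hz`, `fmax`,
#'   `domain`), and `acoustic_scores` (stimulus x n_acoustic_dims
#'   standardized latent acoustic dimensions, for embedding confounds
#'   into EEG)
#' @export
generate_acoustics <- function(space, stimuli, seed = 1,
                               latent_mixing = 0, n_acoustic_dims = 2,
                               gender_weight = 0.8, vowel_weight = 0.6,
                               noise_weight = 0.5,
                               bin_hz = 100, fmax = 8000) {
  n_stim <- nrow(stimuli)
  n_latent <- ncol(space$latent_scores)
  if (length(latent_mixing) == 1L)
    latent_mixing <- matrix(latent_mixing, n_latent, n_acoustic_dims)
  latent_mixing <- as.matrix(latent_mixing)
  if (nrow(latent_mixing) != n_latent || ncol(latent_mixing) != n_acoustic_dims)
    stop("`latent_mixing` must be n_latent x n_acoustic_dims")
  sp <- unique(stimuli$speaker_id)
  g <- ifelse(stimuli$speaker_gender == "male", 1, -1)
  vset <- sort(unique(stimuli$vowel))
  v_num <- scale(as.numeric(factor(stimuli$vowel, levels = vset)))[, 1]
  if (!all(is.finite(v_num))) v_num <- rep(0, n_stim)

  with_seed(seed, {
    lat <- space$latent_scores[match(stimuli$speaker_id, sp), , drop = FALSE]
    dims <- lat %*% latent_mixing
    for (k in seq_len(n_acoustic_dims)) {
      dims[, k] <- dims[, k] +
        gender_weight * g * (if (k == 1) 1 else 0.3) +
        vowel_weight * v_num * (if (k == 2 || n_acoustic_dims == 1) 1 else 0.3) +
        noise_weight * rnorm(n_stim)
    }
    dims <- scale(dims)
    attr(dims, "scaled:center") <- attr(dims, "scaled:scale") <- NULL
    colnames(dims) <- paste0("adim", seq_len(n_acoustic_dims))
    rownames(dims) <- stimuli$stimulus_id

    # 13 measures: 4 families (pitch/formants, harmonic source shape,
    # noise/periodicity, energy) with family-specific loadings on the
    # acoustic dimensions plus measure noise, on realistic scales.
    meas <- measure_catalog()
    d1 <- dims[, 1]
    d2 <- if (n_acoustic_dims >= 2) dims[, 2] else rep(0, n_stim)
    fam_scores <- cbind(
      pitch    = -0.9 * d1 + 0.25 * rnorm(n_stim),
      formant  = 0.9 * d2 + 0.25 * rnorm(n_stim),
      harmonic = 0.85 * d1 + 0.3 * rnorm(n_stim),
      noiseq   = 0.85 * d2 + 0.3 * rnorm(n_stim)
    )
    feat <- matrix(NA_real_, n_stim, nrow(meas))
    colnames(feat) <- meas$name
    for (i in seq_len(nrow(meas))) {
      z <- fam_scores[, meas$family[i]] +
        meas$noise[i] * rnorm(n_stim)
      feat[, i] <- meas$mean[i] + meas$sd[i] * z
    }
    # formants must stay positive and ordered; rebuild them from a
    # base spacing modulated by the formant family score
    spacing <- 1000 * exp(0.12 * fam_scores[, "formant"])
    f1 <- 350 + 150 * exp(0.2 * fam_scores[, "formant"]) + 40 * v_num
    feat[, "F1"] <- f1
    feat[, "F2"] <- f1 + spacing * (1 + 0.15 * v_num)
    feat[, "F3"] <- feat[, "F2"] + spacing
    feat[, "F4"] <- feat[, "F3"] + spacing
    feat[, "DF"] <- vapply(seq_len(n_stim), function(i)
      formant_dispersion(feat[i, c("F1", "F2", "F3", "F4")]), numeric(1))
    feat[, "F0_mean"] <- pmax(60, feat[, "F0_mean"])

    features <- data.frame(stimulus_id = stimuli$stimulus_id, feat,
                           stringsAsFactors = FALSE)
    class(features) <- c("acoustic_features", "data.frame")

    # LTAS: smooth source spectrum (tilt varies with speaker gender)
    # with formant-like bumps (location varies with vowel), linear
    # power.  The latent acoustic dimensions deliberately do not enter
    # the LTAS: they describe the fine-grained measure table, so the
    # degree of overlap between the LTAS RDM and the feature-PCA RDMs
    # stays controllable.
    freqs <- seq(bin_hz / 2, fmax - bin_hz / 2, by = bin_hz)
    spectra <- matrix(0, n_stim, length(freqs))
    for (i in seq_len(n_stim)) {
      tilt_db_oct <- -6 + 1.5 * g[i]
      base_db <- tilt_db_oct * log2(pmax(freqs, 50) / 100)
      # formant bumps at vowel-prototype positions (vowel identity and
      # gender shape the LTAS; per-speaker formant detail stays in the
      # measure table)
      p1 <- 500 + 40 * v_num[i] - 30 * g[i]
      psp <- 1000 * (1 + 0.15 * v_num[i]) - 60 * g[i]
      bump <- rep(0, length(freqs))
      for (f in p1 + psp * 0:3)
        bump <- bump + 12 * exp(-0.5 * ((freqs - f) / 180)^2)
      noise_db <- rnorm(length(freqs), sd = 0.5)
      spectra[i, ] <- 10^((base_db + bump + noise_db) / 10)
    }
    rownames(spectra) <- stimuli$stimulus_id
    ltas <- structure(list(spectra = spectra, bin_hz = bin_hz,
                           fmax = fmax, freqs = freqs, domain = "linear"),
                      class = "ltas_matrix")
    list(features = features, ltas = ltas, acoustic_scores = dims)
  })
}

# Names, family memberships and scales of the 13 acoustic measures.
measure_catalog <- function() {
  data.frame(
    name = c("F0_mean", "F1", "F2", "F3", "F4", "DF", "H1H2", "H2H4",
             "H4H2k", "H2kH5k", "CPP", "Energy", "HNR"),
    family = c("pitch", "formant", "formant", "formant", "formant",
               "formant", "harmonic", "harmonic", "harmonic", "harmonic",
               "noiseq", "noiseq", "noiseq"),
    mean = c(160, 500, 1500, 2500, 3500, 1000, 4, 3, 2, 1, 15, 65, 18),
    sd = c(45, 80, 200, 250, 300, 80, 2, 1.5, 1.2, 1, 3, 5, 4),
    noise = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.4, 0.4, 0.5, 0.5,
              0.4, 0.5, 0.4),
    stringsAsFactors = FALSE
  )
}
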