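#' Describe the ground-truth signal embedded in synthetic EEG
#'
#' Bundles everything that determines the deterministic part of the
#' synthetic scalp signal: which latent trait dimension drives the
#' scalp in which time window and with which spatial pattern, the
#' spatial patterns and window of the acoustic confound, and the
#' signal-to-noise amplitude ratio.
#'
#' @param effect_windows numeric matrix n_latent x 2 (start, end in ms)
#'   giving, per latent dimension, the window in which it drives the
#'   scalp signal
#' @param scalp_patterns numeric matrix n_latent x channels of spatial
#'   patterns (each row is scaled internally to unit RMS)
#' @param acoustic_patterns optional numeric matrix n_acoustic_dims x
#'   channels for the acoustic confound term (NULL = no confound)
#' @param acoustic_windows numeric matrix n_acoustic_dims x 2 (ms)
#' @param snr amplitude ratio of each unit-score effect to the
#'   per-sample noise SD
#' @param acoustic_gain multiplier on the acoustic-confound amplitude
#'   relative to `snr`
#' @param taper Tukey taper fraction of the temporal kernel in (0, 1]:
#'   the kernel is flat over the central `1 - taper` of the window and
#'   cosine-tapered over `taper / 2` at each edge; `taper = 1` is the
#'   raised-cosine window
#' @param seed integer seed recorded with the truth
#' @return object of class `synthetic_truth`
#' @export
synthetic_truth <- function(effect_windows, scalp_patterns,
                            acoustic_patterns = NULL,
                            acoustic_windows = NULL,
                            snr = 1, acoustic_gain = 1, taper = 0.5,
                            seed = 1) {
  if (taper <= 0 || taper > 1) stop("`taper` must be in (0, 1]")
  effect_windows <- matrix(as.numeric(effect_windows), ncol = 2)
  if (any(effect_windows[, 1] >= effect_windows[, 2]))
    stop("effect windows must have start < end")
  scalp_patterns <- as.matrix(scalp_patterns)
  if (nrow(scalp_patterns) != nrow(effect_windows))
    stop("one effect window per scalp pattern row required")
  if (!is.null(acoustic_patterns)) {
    acoustic_patterns <- as.matrix(acoustic_patterns)
    if (is.null(acoustic_windows))
      stop("`acoustic_windows` required with `acoustic_patterns`")
    acoustic_windows <- matrix(as.numeric(acoustic_windows), ncol = 2)
    if (nrow(acoustic_windows) != nrow(acoustic_patterns))
      stop("one acoustic window per acoustic pattern row required")
  }
  structure(list(effect_windows = effect_windows,
                 scalp_patterns = scalp_patterns,
                 acoustic_patterns = acoustic_patterns,
                 acoustic_windows = acoustic_windows,
                 snr = snr, acoustic_gain = acoustic_gain,
                 taper = taper, seed = seed),
            class = "synthetic_truth")
}

#' Random unit-RMS scalp patterns
#'
#' Smooth random spatial patterns over the montage, one per row,
#' normalized to unit root-mean-square across channels.
#' @param n number of patterns
#' @param positions channels x 3 unit-sphere electrode positions
#' @param smoothness spatial correlation length (radians)
#' @param seed integer seed
#' @export
random_scalp_patterns <- function(n, positions, smoothness = 0.8, seed = 1) {
  K <- exp(-angular_distance(positions) / smoothness)
  L <- chol(K + diag(1e-8, nrow(K)))
  with_seed(seed, {
    P <- matrix(rnorm(n * nrow(K)), n) %*% L
    P / sqrt(rowMeans(P^2))
  })
}

# Great-circle distance matrix between unit-sphere positions.
angular_distance <- function(positions) {
  cosang <- tcrossprod(positions / sqrt(rowSums(positions^2)))
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  acos(cosang)
}

# Tukey (tapered-cosine) temporal kernel on [start, end] ms, peak 1:
# flat over the central (1 - taper) fraction, cosine tapers at both
# ends.  taper = 1 gives the raised-cosine (Hann) window.
tukey_kernel <- function(times, start, end, taper = 0.5) {
  k <- numeric(length(times))
  w <- end - start
  edge <- taper * w / 2
  u <- times - start
  inside <- u >= 0 & u <= w
  ui <- u[inside]
  ki <- rep(1, length(ui))
  lo <- ui < edge
  hi <- ui > w - edge
  ki[lo] <- 0.5 * (1 - cos(pi * ui[lo] / edge))
  ki[hi] <- 0.5 * (1 - cos(pi * (w - ui[hi]) / edge))
  k[inside] <- ki
  k
}

#' Generate synthetic EEG epochs with an embedded representational
#' geometry
#'
#' Every trial's deterministic part is the sum over latent trait
#' dimensions of (speaker latent score x scalp pattern x temporal
#' window kernel), plus an optional acoustic-confound term (acoustic
#' dimension score x pattern x kernel), scaled by `truth$snr`.  The
#' kernel is a Tukey (tapered-cosine) window over the effect window,
#' flat over its central part; `truth$taper = 1` gives the fully
#' tapered raised-cosine case.  Trials
#' of the same stimulus share the deterministic part exactly.  Noise is
#' stationary Gaussian with first-order spatial correlation between
#' neighboring electrodes (r about 0.6) and a 1/f-shaped temporal
#' spectrum, unit SD per sample.  Vigilance trials carry noise only.
#'
#' @param design an `experiment_design`
#' @param space a `latent_person_space`
#' @param truth a `synthetic_truth`
#' @param n_channels number of channels (first `n_channels` of the
#'   standard montage, always including Tp9/Tp10)
#' @param sfreq sampling frequency in Hz (1000 reproduces the 1-ms
#'   grid; 100 gives the reduced desk grid)
#' @param seed integer seed
#' @param acoustic_scores stimulus x n_acoustic_dims matrix (from
#'   [generate_acoustics()]) if `truth` has acoustic patterns
#' @param window_ms epoch window (ms relative to onset)
#' @return an [epoch_array()]
#' @export
generate_eeg <- function(design, space, truth, n_channels = 32,
                         sfreq = 1000, seed = 1,
                         acoustic_scores = NULL,
                         window_ms = c(-100, 700)) {
  times <- seq(window_ms[1], window_ms[2], by = 1000 / sfreq)
  if (any(truth$effect_windows[, 1] < window_ms[1]) ||
      any(truth$effect_windows[, 2] > window_ms[2]))
    stop("effect window outside the epoch window [",
         window_ms[1], ", ", window_ms[2], "] ms")
  mont <- standard_montage()
  if (n_channels < nrow(mont)) {
    keep <- unique(c(head(mont$label, n_channels - 2), "TP9", "TP10"))
    mont <- mont[match(keep, mont$label), , drop = FALSE]
  }
  pos <- as.matrix(mont[, c("x", "y", "z")])
  n_ch <- nrow(pos)
  if (ncol(truth$scalp_patterns) != n_ch)
    stop("scalp patterns have ", ncol(truth$scalp_patterns),
         " channels; montage has ", n_ch)
  n_latent <- ncol(space$latent_scores)
  if (nrow(truth$scalp_patterns) != n_latent)
    stop("one scalp pattern per latent dimension required")
  if (!is.null(truth$acoustic_patterns) && is.null(acoustic_scores))
    stop("`acoustic_scores` required: truth embeds an acoustic confound")

  trials <- design$trials
  stimuli <- design$stimuli
  n_trials <- nrow(trials)
  n_t <- length(times)

  # deterministic per-stimulus signal, channels x time
  patt <- truth$scalp_patterns / sqrt(rowMeans(truth$scalp_patterns^2))
  kern <- t(vapply(seq_len(n_latent), function(k)
    tukey_kernel(times, truth$effect_windows[k, 1],
                 truth$effect_windows[k, 2], truth$taper), numeric(n_t)))
  sig <- vector("list", nrow(stimuli))
  names(sig) <- stimuli$stimulus_id
  sp_idx <- match(stimuli$speaker_id, unique(stimuli$speaker_id))
  for (i in seq_len(nrow(stimuli))) {
    S <- matrix(0, n_ch, n_t)
    for (k in seq_len(n_latent))
      S <- S + space$latent_scores[sp_idx[i], k] *
        outer(patt[k, ], kern[k, ])
    if (!is.null(truth$acoustic_patterns)) {
      ap <- truth$acoustic_patterns /
        sqrt(rowMeans(truth$acoustic_patterns^2))
      for (j in seq_len(nrow(ap))) {
        ak <- tukey_kernel(times, truth$acoustic_windows[j, 1],
                           truth$acoustic_windows[j, 2], truth$taper)
        S <- S + (truth$acoustic_gain %||% 1) *
          acoustic_scores[stimuli$stimulus_id[i], j] * outer(ap[j, ], ak)
      }
    }
    sig[[i]] <- truth$snr * S
  }

  # spatially correlated, 1/f-shaped noise
  spat <- exp(-angular_distance(pos) / noise_spatial_lambda(pos))
  Ls <- chol(spat + diag(1e-8, n_ch))
  shape <- one_over_f_shape(n_t)
  data <- array(0, c(n_trials, n_ch, n_t))
  with_seed(seed, {
    for (tr in seq_len(n_trials)) {
      white <- matrix(rnorm(n_ch * n_t), n_ch, n_t)
      tempo <- t(Re(stats::mvfft(stats::mvfft(t(white)) * shape,
                                 inverse = TRUE))) / n_t
      tempo <- tempo / sd(tempo)
      noise <- crossprod(Ls, tempo)
      s <- sig[[trials$stimulus_id[tr]]]
      data[tr, , ] <- if (is.null(s)) noise else s + noise
    }
  })
  meta <- data.frame(stimulus_id = trials$stimulus_id,
                     trial_type = trials$trial_type,
                     keep_flag = TRUE, block = trials$block,
                     stringsAsFactors = FALSE)
  epoch_array(data, times, mont$label, pos, meta, reference = "recording")
}

# Spatial correlation length chosen so that neighboring electrodes
# correlate at about 0.6.
noise_spatial_lambda <- function(positions) {
  d <- angular_distance(positions)
  diag(d) <- NA
  nb <- median(apply(d, 1, min, na.rm = TRUE))
  nb / (-log(0.6))
}

# Amplitude shaping |H(f)| ~ 1/sqrt(f) (power ~ 1/f), DC kept finite.
one_over_f_shape <- function(n) {
  k <- 0:(n - 1)
  fi <- pmin(k, n - k)  # mirror for negative frequencies
  1 / sqrt(pmax(fi, 1))
}
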