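#' Detect erroneous EEG channels in the frequency domain
#'
#' Joint-probability screening of channels: per-channel spectral power
#' is summarized in frequency bins, each bin's values are converted to
#' robust z scores across channels, and a per-channel joint
#' log-probability statistic (mean Gaussian log density of its robust z
#' scores) is computed.  Channels whose statistic lies more than
#' `threshold_sd` robust SDs (median absolute deviation units) below
#' the channel median are flagged.
#'
#' @param epochs an `epoch_array`
#' @param threshold_sd flagging threshold in robust SD units
#' @param bin_hz frequency bin width in Hz
#' @return object of class `channel_qc_report`: list with
#'   `bad_channels`, `per_channel_statistic`, `threshold_sd`
#' @export
detect_bad_channels <- function(epochs, threshold_sd = 4, bin_hz = 1) {
  d <- dim(epochs$data)
  if (d[2L] < 2) stop("need at least 2 channels")
  sf <- epoch_sfreq(epochs)
  n_t <- d[3L]
  # average power spectrum per channel over trials
  freqs <- (0:(n_t - 1)) / n_t * sf
  half <- freqs < sf / 2 & freqs > 0
  pow <- matrix(0, d[2L], sum(half))
  for (ch in seq_len(d[2L])) {
    X <- matrix(epochs$data[, ch, , drop = FALSE], d[1L], n_t)
    P <- abs(stats::mvfft(t(X)))^2 / n_t  # time x trials
    pow[ch, ] <- rowMeans(P)[half]
  }
  bins <- floor(freqs[half] / bin_hz)
  logp <- t(apply(pow, 1, function(p) tapply(log(p + 1e-300), bins, mean)))
  # robust z per bin across channels
  med <- apply(logp, 2, median)
  madv <- apply(logp, 2, mad)
  madv[madv < 1e-12] <- Inf  # identical channels: no deviation
  z <- sweep(sweep(logp, 2, med), 2, madv, "/")
  stat <- rowMeans(stats::dnorm(z, log = TRUE))
  s_med <- median(stat)
  s_mad <- mad(stat)
  if (s_mad < 1e-12) {
    bad <- character(0)
  } else {
    dev <- (s_med - stat) / s_mad  # low joint probability = suspicious
    bad <- epochs$channel_labels[is.finite(dev) & dev > threshold_sd]
  }
  if (length(bad) == d[2L])
    stop("all channels flagged as bad; data are degenerate")
  structure(list(bad_channels = bad, per_channel_statistic =
                   setNames(stat, epochs$channel_labels),
                 threshold_sd = threshold_sd),
            class = "channel_qc_report")
}

#' Interpolate bad channels by spherical splines
#'
#' Replaces flagged channels with spherical-spline estimates (Perrin
#' style, order-4 Legendre weighting, 50-term series) computed from the
#' remaining good channels.  Good channels are untouched.
#'
#' @param epochs an `epoch_array`
#' @param bad character vector of channel labels to interpolate
#' @param lambda ridge regularization added to the spline system
#' @return the `epoch_array` with bad channels replaced
#' @export
interpolate_channels <- function(epochs, bad, lambda = 1e-5) {
  if (!length(bad)) return(epochs)
  labs <- epochs$channel_labels
  miss <- setdiff(bad, labs)
  if (length(miss))
    stop("unknown channel(s): ", paste(miss, collapse = ", "))
  good <- setdiff(labs, bad)
  if (length(good) < 4) stop("need at least 4 good channels")
  pos <- epochs$channel_positions
  if (anyNA(pos[bad, , drop = FALSE]))
    stop("missing positions for channels: ", paste(bad, collapse = ", "))
  M <- spline_interp_matrix(pos[good, , drop = FALSE],
                            pos[bad, , drop = FALSE], lambda)
  gi <- match(good, labs); bi <- match(bad, labs)
  d <- dim(epochs$data)
  for (tr in seq_len(d[1L])) {
    G <- epochs$data[tr, gi, , drop = TRUE]
    if (is.null(dim(G))) G <- matrix(G, nrow = length(gi))
    epochs$data[tr, bi, ] <- M %*% G
  }
  epochs
}

# Spherical-spline interpolation operator mapping good-channel values
# to bad-channel estimates (Perrin et al. style; order m = 4).
spline_interp_matrix <- function(good_pos, bad_pos, lambda = 1e-5,
                                 m = 4, n_terms = 50) {
  gn <- good_pos / sqrt(rowSums(good_pos^2))
  bn <- bad_pos / sqrt(rowSums(bad_pos^2))
  Ggg <- spline_g(tcrossprod(gn), m, n_terms)
  Gbg <- spline_g(bn %*% t(gn), m, n_terms)
  n <- nrow(gn)
  A <- rbind(cbind(Ggg + diag(lambda, n), 1), c(rep(1, n), 0))
  # solve for weights of each bad channel: [Gbg 1] %*% solve(A) rows
  W <- cbind(Gbg, 1) %*% solve(A)
  W[, seq_len(n), drop = FALSE]
}

# g(cos gamma) = (1/4pi) * sum_n (2n+1)/(n(n+1))^m P_n(cos gamma)
spline_g <- function(x, m = 4, n_terms = 50) {
  x <- as.matrix(x)
  x[x > 1] <- 1
  x[x < -1] <- -1
  res <- array(0, dim = dim(x))
  P_prev <- array(1, dim = dim(res))        # P_0
  P_curr <- x                               # P_1
  for (n in seq_len(n_terms)) {
    res <- res + (2 * n + 1) / (n * (n + 1))^m * P_curr
    P_next <- ((2 * n + 1) * as.matrix(x) * P_curr - n * P_prev) / (n + 1)
    P_prev <- P_curr
    P_curr <- P_next
  }
  res / (4 * pi)
}

#' Flag trials exceeding a peak-to-peak amplitude threshold
#'
#' A trial is rejected when max minus min on any single channel exceeds
#' `peak_to_peak_uv`.  Rejection only clears the `keep_flag`; retained
#' samples are never altered.
#'
#' @param epochs an `epoch_array`
#' @param peak_to_peak_uv threshold in microvolts
#' @return the `epoch_array` with updated `keep_flag`
#' @export
reject_amplitude_artifacts <- function(epochs, peak_to_peak_uv = 150) {
  d <- dim(epochs$data)
  ptp <- apply(epochs$data, 1, function(m)
    max(apply(m, 1, function(ch) diff(range(ch)))))
  bad <- ptp > peak_to_peak_uv
  epochs$trial_meta$keep_flag <- epochs$trial_meta$keep_flag & !bad
  attr(epochs, "n_rejected_amplitude") <- sum(bad)
  epochs
}

#' Flag trials with excess high-frequency (muscle-like) power
#'
#' Per trial, power above `hf_hz` is summed over channels; trials whose
#' log power z score across trials exceeds `z_threshold` are flagged.
#'
#' @param epochs an `epoch_array`
#' @param hf_hz high-frequency cutoff in Hz
#' @param z_threshold z-score threshold
#' @return the `epoch_array` with updated `keep_flag`
#' @export
reject_muscle_artifacts <- function(epochs, hf_hz = 30, z_threshold = 4) {
  sf <- epoch_sfreq(epochs)
  d <- dim(epochs$data)
  n_t <- d[3L]
  freqs <- (0:(n_t - 1)) / n_t * sf
  sel <- freqs > hf_hz & freqs < sf / 2
  if (!any(sel)) return(epochs)  # nothing above the cutoff at this rate
  hp <- vapply(seq_len(d[1L]), function(tr) {
    P <- abs(stats::mvfft(t(epochs$data[tr, , , drop = TRUE])))^2
    sum(P[sel, ])
  }, numeric(1))
  z <- (log(hp + 1e-300) - mean(log(hp + 1e-300))) / sd(log(hp + 1e-300))
  bad <- is.finite(z) & z > z_threshold
  epochs$trial_meta$keep_flag <- epochs$trial_meta$keep_flag & !bad
  attr(epochs, "n_rejected_muscle") <- sum(bad)
  epochs
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero group delay) Butterworth filtering per trial
#' and channel, with reflect padding at the epoch edges to suppress
#' filter transients.
#'
#' @param epochs an `epoch_array`
#' @param low_hz,high_hz band edges in Hz; set `low_hz = 0` for a pure
#'   low-pass
#' @param order filter order
#' @param pad_s reflect-padding duration per edge in seconds
#' @return the filtered `epoch_array`
#' @export
bandpass_filter <- function(epochs, low_hz = 0.1, high_hz = 30,
                            order = 4, pad_s = 1) {
  sf <- epoch_sfreq(epochs)
  nyq <- sf / 2
  if (high_hz >= nyq) stop("high_hz must be below the Nyquist frequency ", nyq)
  if (low_hz < 0 || low_hz >= high_hz) stop("invalid band: ", low_hz,
                                            "-", high_hz, " Hz")
  if (low_hz > 0) {
    flt <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else {
    flt <- signal::butter(order, high_hz / nyq, type = "low")
  }
  d <- dim(epochs$data)
  n_t <- d[3L]
  npad <- min(round(pad_s * sf), n_t - 1)
  for (tr in seq_len(d[1L])) for (ch in seq_len(d[2L])) {
    x <- epochs$data[tr, ch, ]
    xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
            2 * x[n_t] - rev(x[(n_t - npad):(n_t - 1)]))
    y <- signal::filtfilt(flt, xp)
    epochs$data[tr, ch, ] <- y[(npad + 1):(npad + n_t)]
  }
  epochs
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude in the baseline
#' window.
#'
#' @param epochs an `epoch_array`
#' @param window_ms length-2 numeric baseline window (ms)
#' @return the corrected `epoch_array`
#' @export
baseline_correct <- function(epochs, window_ms = c(-100, 0)) {
  sel <- epochs$times >= window_ms[1] & epochs$times <= window_ms[2]
  if (!any(sel)) stop("baseline window [", window_ms[1], ", ",
                      window_ms[2], "] ms contains no samples")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over time
  epochs
}

#' Re-reference epochs to the average of reference channels
#'
#' @param epochs an `epoch_array`
#' @param reference_labels channel labels to average as reference
#'   (default: the temporal electrodes Tp9/Tp10, approximating a linked
#'   mastoid reference)
#' @return the re-referenced `epoch_array`
#' @export
rereference <- function(epochs, reference_labels = c("TP9", "TP10")) {
  idx <- match(toupper(reference_labels), toupper(epochs$channel_labels))
  if (anyNA(idx))
    stop("reference channel(s) not found: ",
         paste(reference_labels[is.na(idx)], collapse = ", "))
  d <- dim(epochs$data)
  ref <- epochs$data[, idx, , drop = FALSE]
  refm <- apply(ref, c(1, 3), mean)  # trials x time
  for (ch in seq_len(d[2L]))
    epochs$data[, ch, ] <- epochs$data[, ch, ] - refm
  epochs$reference <- paste(epochs$channel_labels[idx], collapse = "+")
  epochs
}

#' Run the canonical preprocessing chain
#'
#' Order: bad-channel detection, spherical-spline interpolation,
#' optional 100 Hz low-pass, muscle and amplitude artifact flagging,
#' band-pass filtering, baseline correction, re-referencing.  A QC
#' report with per-stage counts is attached.
#'
#' @param epochs an `epoch_array`
#' @param config list of stage parameters (see [pipeline_config()]);
#'   recognized entries: `bad_channel_sd`, `peak_to_peak_uv`, `low_hz`,
#'   `high_hz`, `filter_order`, `baseline_ms`, `reference_labels`,
#'   `lowpass_pre_hz` (NULL disables the pre-low-pass)
#' @return the preprocessed `epoch_array`; QC report in
#'   `attr(, "qc_report")`
#' @export
preprocess_epochs <- function(epochs, config = list()) {
  cfg <- utils::modifyList(list(
    bad_channel_sd = 4, peak_to_peak_uv = 150, low_hz = 0.1,
    high_hz = 30, filter_order = 4, baseline_ms = c(-100, 0),
    reference_labels = c("TP9", "TP10"), lowpass_pre_hz = 100,
    muscle_z = 4), config)
  qc <- detect_bad_channels(epochs, cfg$bad_channel_sd)
  epochs <- interpolate_channels(epochs, qc$bad_channels)
  sf <- epoch_sfreq(epochs)
  if (!is.null(cfg$lowpass_pre_hz) && cfg$lowpass_pre_hz < sf / 2)
    epochs <- bandpass_filter(epochs, 0, cfg$lowpass_pre_hz,
                              cfg$filter_order)
  epochs <- reject_muscle_artifacts(epochs, z_threshold = cfg$muscle_z)
  n_muscle <- attr(epochs, "n_rejected_muscle") %||% 0L
  epochs <- reject_amplitude_artifacts(epochs, cfg$peak_to_peak_uv)
  n_amp <- attr(epochs, "n_rejected_amplitude") %||% 0L
  epochs <- bandpass_filter(epochs, cfg$low_hz, cfg$high_hz,
                            cfg$filter_order)
  epochs <- baseline_correct(epochs, cfg$baseline_ms)
  epochs <- rereference(epochs, cfg$reference_labels)
  n_tr <- nrow(epochs$trial_meta)
  attr(epochs, "qc_report") <- list(
    bad_channels = qc$bad_channels,
    n_channels_interpolated = length(qc$bad_channels),
    n_rejected_muscle = n_muscle,
    n_rejected_amplitude = n_amp,
    pct_trials_rejected = 100 * (n_tr - sum(epochs$trial_meta$keep_flag)) / n_tr,
    config = cfg)
  epochs
}
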