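#' Long-term average spectrum of a waveform
#'
#' Welch-style averaged periodogram: the waveform is cut into
#' 50%-overlapping Hann-windowed segments, periodograms are averaged,
#' and the resulting power spectrum is aggregated into fixed-width
#' frequency bins up to `fmax`.
#'
#' @param waveform numeric vector of samples
#' @param sfreq sampling frequency (Hz)
#' @param bin_hz bin width (Hz)
#' @param fmax maximum frequency (Hz), at most the Nyquist frequency
#' @param segment_s segment length in seconds
#' @return list with `power_db` (per-bin power in dB), `power`
#'   (linear), `freqs` (bin centers, Hz), `bin_hz`
#' @export
compute_ltas <- function(waveform, sfreq, bin_hz = 100, fmax = 8000,
                         segment_s = 0.03) {
  if (!length(waveform)) stop("empty waveform")
  if (all(waveform == 0)) stop("silent (all-zero) waveform")
  if (fmax > sfreq / 2) stop("fmax exceeds the Nyquist frequency ", sfreq / 2)
  n <- length(waveform)
  L <- min(n, max(16, 2^round(log2(segment_s * sfreq))))
  hop <- max(1, L %/% 2)
  starts <- seq(1, n - L + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  P <- numeric(L)
  for (s in starts) {
    seg <- waveform[s:(s + L - 1)] * w
    P <- P + abs(fft(seg))^2
  }
  P <- P / (length(starts) * sum(w^2) * sfreq) * 2
  freqs <- (seq_len(L) - 1) / L * sfreq
  sel <- freqs > 0 & freqs < sfreq / 2
  bins <- floor(freqs[sel] / bin_hz)
  keep <- bins < fmax / bin_hz
  pow <- tapply(P[sel][keep], bins[keep], mean)
  centers <- (as.numeric(names(pow)) + 0.5) * bin_hz
  pow <- as.numeric(pow)
  list(power_db = 10 * log10(pmax(pow, 1e-300)), power = pow,
       freqs = centers, bin_hz = bin_hz)
}

#' Cosine dissimilarity of two vectors
#'
#' `1 - (u . v) / (||u|| ||v||)`; ranges over [0, 2] and is 0 iff the
#' vectors are proportional with positive scale.
#'
#' @param u,v numeric vectors of equal length
#' @return the cosine dissimilarity
#' @export
cosine_dissimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine dissimilarity undefined for a zero vector")
  1 - sum(u * v) / (nu * nv)
}

#' Formant dispersion
#'
#' Summarizes the spacing of the first four formants.  The default
#' (`method = "regression"`) is the slope of the least-squares
#' regression of formant frequency on formant number; the mean-spacing
#' reading `(F4 - F1) / 3` is available as `method = "spacing"`.  Both
#' agree exactly when the formants are an arithmetic progression.
#'
#' @param formants numeric vector F1..F4 (Hz), strictly increasing
#' @param method `"regression"` or `"spacing"`
#' @return dispersion in Hz
#' @export
formant_dispersion <- function(formants, method = c("regression", "spacing")) {
  method <- match.arg(method)
  f <- as.numeric(formants)
  if (length(f) < 2) stop("need at least 2 formants")
  if (any(diff(f) <= 0))
    stop("formants must be strictly increasing (got ",
         paste(round(f), collapse = ", "), ")")
  i <- seq_along(f)
  switch(method,
         regression = sum((i - mean(i)) * (f - mean(f))) / sum((i - mean(i))^2),
         spacing = (f[length(f)] - f[1]) / (length(f) - 1))
}

#' Acoustic RDMs: LTAS cosine dissimilarity and PCA-score distances
#'
#' Reduces the 13 perceptually salient acoustic measures with the
#' shared PCA-with-oblimin implementation (components retained at
#' eigenvalue > 1), builds one absolute-score-difference RDM per
#' retained component, and one RDM of pairwise cosine dissimilarities
#' of the LTAS (computed on linear power spectra).
#'
#' @param features an `acoustic_features` table (13 measure columns +
#'   `stimulus_id`)
#' @param ltas an `ltas_matrix`
#' @return object of class `acoustic_rdm_set`: `ltas_rdm`, `pc_rdms`
#'   (list of matrices), `pca` (the `pca_solution`)
#' @export
acoustic_pca_rdms <- function(features, ltas) {
  meas <- measure_catalog()$name
  miss <- setdiff(meas, names(features))
  if (length(miss))
    stop("feature table lacks measure(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(features[, meas])
  if (anyNA(X)) stop("feature table has missing values")
  stims <- features$stimulus_id
  pca <- pca_oblimin(X)
  rownames(pca$component_scores) <- stims
  if (pca$n_components < 1) stop("no retained acoustic component")
  pc_rdms <- lapply(seq_len(pca$n_components), function(j) {
    s <- pca$component_scores[, j]
    m <- abs(outer(s, s, "-"))
    dimnames(m) <- list(stims, stims)
    m
  })
  names(pc_rdms) <- colnames(pca$pattern_loadings)
  sp <- ltas$spectra
  if (!is.null(ltas$domain) && ltas$domain == "dB") sp <- 10^(sp / 10)
  n <- nrow(sp)
  lr <- matrix(0, n, n, dimnames = list(stims, stims))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    lr[i, j] <- lr[j, i] <- cosine_dissimilarity(sp[i, ], sp[j, ])
  structure(list(ltas_rdm = lr, pc_rdms = pc_rdms, pca = pca),
            class = "acoustic_rdm_set")
}
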