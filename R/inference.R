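#' Inference configuration
#'
#' @param z_threshold_one_sided cluster-forming threshold for
#'   one-sample tests (z scale, strict inequality)
#' @param z_threshold_two_sided threshold for paired model comparisons
#' @param n_iterations number of sign-flip resampling iterations
#' @param alpha family-wise significance level
#' @param seed integer seed for the resampling
#' @return object of class `inference_config`
#' @export
inference_config <- function(z_threshold_one_sided = 1.64,
                             z_threshold_two_sided = 1.96,
                             n_iterations = 10000, alpha = 0.05,
                             seed = 1) {
  if (z_threshold_one_sided <= 0 || z_threshold_two_sided <= 0)
    stop("thresholds must be positive")
  if (n_iterations < 100) stop("`n_iterations` must be >= 100")
  structure(list(z_threshold_one_sided = z_threshold_one_sided,
                 z_threshold_two_sided = z_threshold_two_sided,
                 n_iterations = as.integer(n_iterations), alpha = alpha,
                 seed = as.integer(seed)),
            class = "inference_config")
}

#' Standard-normal quantile for a significance threshold
#'
#' @param alpha significance level in (0, 1)
#' @param sides "one" or "two"
#' @return the z threshold: `qnorm(1 - alpha)` one-sided,
#'   `qnorm(1 - alpha / 2)` two-sided
#' @export
normal_quantile_threshold <- function(alpha, sides = c("one", "two")) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)")
  sides <- match.arg(sides)
  qnorm(1 - if (sides == "one") alpha else alpha / 2)
}

# One-sample t statistics per column, and their z equivalents via the
# probability-integral transform through the t CDF (tail-safe).
column_t <- function(data) {
  n <- nrow(data)
  m <- colMeans(data)
  s <- sqrt((colSums(data^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[s == 0 & m == 0] <- 0
  t
}

t_to_z <- function(t, df) {
  z <- numeric(length(t))
  pos <- !is.na(t) & t >= 0
  z[pos] <- qnorm(pt(t[pos], df, lower.tail = FALSE), lower.tail = FALSE)
  z[!pos & !is.na(t)] <- qnorm(pt(t[!pos & !is.na(t)], df))
  z[is.na(t)] <- NA_real_
  z
}

# Contiguous runs of TRUE; returns data.frame(start, end, size).
find_runs <- function(mask) {
  mask[is.na(mask)] <- FALSE
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             size = r$lengths[keep])
}

# Maximum suprathreshold cluster size per row of a z matrix.
max_cluster_sizes <- function(z, threshold, two_sided = FALSE) {
  supra <- if (two_sided) abs(z) > threshold else z > threshold
  apply(supra, 1, function(m) {
    r <- find_runs(m)
    if (nrow(r)) max(r$size) else 0L
  })
}

# Shared core of the one-sample and paired cluster tests.
cluster_core <- function(data, threshold, two_sided, config, times) {
  n <- nrow(data)
  if (n < 2) stop("need >= 2 participants")
  df <- n - 1
  # undefined (NA) or zero-variance time points never enter clusters
  bad <- apply(data, 2, function(x) anyNA(x) || sd(x) == 0)
  if (any(bad))
    warning(sum(bad), " undefined or zero-variance time point(s); ",
            "excluded from clusters")
  data[, bad] <- 0
  t_obs <- column_t(data)
  z_obs <- t_to_z(t_obs, df)
  z_obs[bad] <- NA_real_
  supra <- if (two_sided) abs(z_obs) > threshold else z_obs > threshold
  clusters <- find_runs(supra)

  # sign-flip null of the maximum cluster size
  sq <- colSums(data^2)
  null_max <- with_seed(config$seed, {
    signs <- matrix(sample(c(-1, 1), config$n_iterations * n,
                           replace = TRUE), config$n_iterations, n)
    M <- (signs %*% data) / n
    S2 <- sweep(-n * M^2, 2, sq, "+") / (n - 1)
    Tm <- M / sqrt(S2 / n)
    Tm[!is.finite(Tm)] <- 0
    Zm <- matrix(t_to_z(Tm, df), nrow(Tm), ncol(Tm))
    max_cluster_sizes(Zm, threshold, two_sided)
  })

  if (nrow(clusters)) {
    clusters$corrected_p <- vapply(clusters$size, function(sz)
      mean(null_max >= sz), numeric(1))
    # z equivalent of the corrected p (floored at the resolution of the
    # null distribution)
    pfloor <- pmax(clusters$corrected_p, 1 / (config$n_iterations + 1))
    clusters$cluster_z <- qnorm(1 - pfloor)
    clusters$start_ms <- times[clusters$start]
    clusters$end_ms <- times[clusters$end]
    clusters <- clusters[order(clusters$start), , drop = FALSE]
  } else {
    clusters$corrected_p <- numeric(0)
    clusters$cluster_z <- numeric(0)
    clusters$start_ms <- numeric(0)
    clusters$end_ms <- numeric(0)
  }
  sig <- clusters[!is.na(clusters$corrected_p) &
                    clusters$corrected_p < config$alpha, , drop = FALSE]

  # peak: maximum group mean, inside significant clusters when any
  gm <- colMeans(data)
  cand <- if (nrow(sig)) unlist(mapply(seq, sig$start, sig$end,
                                       SIMPLIFY = FALSE)) else
    seq_along(gm)
  peak_idx <- cand[which.max(gm[cand])]  # earliest wins on ties
  structure(list(clusters = clusters, significant = sig,
                 z = z_obs, t = t_obs, times = times,
                 peak_time_ms = times[peak_idx],
                 peak_statistic = gm[peak_idx],
                 threshold = threshold, two_sided = two_sided,
                 n_iterations = config$n_iterations,
                 alpha = config$alpha),
            class = "cluster_result")
}

#' One-sample permutation cluster-size inference
#'
#' Per time point, a one-sample t statistic against zero is converted
#' to z; contiguous runs of z above the one-sided threshold form
#' clusters scored by size.  The null distribution of the maximum
#' cluster size is built by sign-flip resampling of the participant
#' time courses, and a cluster's corrected p is the fraction of null
#' maxima at least as large.
#'
#' @param data numeric participants x time matrix
#' @param config an `inference_config`
#' @param times optional time axis (ms); defaults to column indices
#' @return object of class `cluster_result` with `clusters`
#'   (start/end/size/corrected_p/cluster_z/start_ms/end_ms),
#'   `significant`, `z`, `peak_time_ms`, `peak_statistic`
#' @export
cluster_onesample <- function(data, config = inference_config(),
                              times = NULL) {
  data <- as.matrix(data)
  times <- times %||% seq_len(ncol(data))
  cluster_core(data, config$z_threshold_one_sided, FALSE, config, times)
}

#' Paired two-sample permutation cluster-size inference
#'
#' Tests `data_a - data_b` with matched participants, using the
#' two-sided threshold and two-sided suprathreshold clusters.
#'
#' @param data_a,data_b participants x time matrices (matched rows)
#' @param config an `inference_config`
#' @param times optional time axis (ms)
#' @return a `cluster_result` for the paired difference
#' @export
cluster_paired <- function(data_a, data_b, config = inference_config(),
                           times = NULL) {
  data_a <- as.matrix(data_a); data_b <- as.matrix(data_b)
  if (!all(dim(data_a) == dim(data_b)))
    stop("`data_a` and `data_b` must have matching dimensions")
  times <- times %||% seq_len(ncol(data_a))
  cluster_core(data_a - data_b, config$z_threshold_two_sided, TRUE,
               config, times)
}

#' Peak statistics of a group time course
#'
#' Locates the peak of the group mean (restricted to significant
#' clusters when a `cluster_result` is supplied; earliest time wins on
#' ties) and reports the one-sample t against the null level, degrees
#' of freedom and Cohen's d = (mean - null) / SD at the peak.
#'
#' @param data participants x time matrix
#' @param null_level the no-effect value (0 for correlations, 0.5 for
#'   decoding accuracy)
#' @param times optional time axis (ms)
#' @param clusters optional `cluster_result` restricting the peak search
#' @return object of class `timecourse_stats`: `t_value`, `df`,
#'   `cohens_d`, `time_ms`, `peak_mean`
#' @export
peak_statistics <- function(data, null_level = 0, times = NULL,
                            clusters = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need >= 2 participants")
  times <- times %||% seq_len(ncol(data))
  gm <- colMeans(data)
  cand <- seq_along(gm)
  if (!is.null(clusters) && nrow(clusters$significant))
    cand <- unlist(mapply(seq, clusters$significant$start,
                          clusters$significant$end, SIMPLIFY = FALSE))
  peak <- cand[which.max(gm[cand])]
  x <- data[, peak] - null_level
  n <- nrow(data)
  s <- sd(x)
  t_val <- mean(x) / (s / sqrt(n))
  structure(list(t_value = t_val, df = n - 1L,
                 cohens_d = mean(x) / s, time_ms = times[peak],
                 peak_mean = gm[peak]),
            class = "timecourse_stats")
}
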