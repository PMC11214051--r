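#' Decoding configuration
#'
#' Parameters of the cross-validated pairwise decoding that builds the
#' neural RDM: number of subaveraging splits (= cross-validation
#' folds), number of subaveraging permutations to average over, the
#' classifier (linear SVM), its cost parameter and the covariance
#' shrinkage policy of the multivariate noise normalization.
#'
#' @param n_splits number of splits/folds (>= 2)
#' @param n_permutations number of random subaveraging draws (>= 1)
#' @param classifier only `"linear_svm"` is supported
#' @param svm_cost SVM cost parameter C
#' @param shrinkage_mode `"auto"` (analytic Ledoit-Wolf-style
#'   intensity) or `"fixed"`
#' @param shrinkage fixed shrinkage intensity in [0, 1] (used when
#'   `shrinkage_mode = "fixed"`)
#' @param seed integer seed driving the split assignments
#' @return object of class `decoding_config`
#' @export
decoding_config <- function(n_splits = 5, n_permutations = 50,
                            classifier = "linear_svm", svm_cost = 1,
                            shrinkage_mode = c("auto", "fixed"),
                            shrinkage = 0.1, seed = 1) {
  if (n_splits < 2) stop("`n_splits` must be >= 2")
  if (n_permutations < 1) stop("`n_permutations` must be >= 1")
  classifier <- match.arg(classifier)
  shrinkage_mode <- match.arg(shrinkage_mode)
  structure(list(n_splits = as.integer(n_splits),
                 n_permutations = as.integer(n_permutations),
                 classifier = classifier, svm_cost = svm_cost,
                 shrinkage_mode = shrinkage_mode, shrinkage = shrinkage,
                 seed = as.integer(seed)),
            class = "decoding_config")
}

#' Subaverage trials into pseudo-trials
#'
#' Randomly assigns the retained experimental trials of every stimulus
#' to `n_splits` splits (balanced within stimulus, remainder spread at
#' random) and averages each split into one pseudo-trial.  The split
#' assignment is fully determined by `(config$seed, permutation_index)`.
#'
#' @param epochs an `epoch_array`
#' @param config a `decoding_config`
#' @param permutation_index index of the subaveraging draw (>= 1)
#' @return object of class `pseudo_trial_set`: `averages` (stimulus x
#'   split x channels x time), `counts` (stimulus x split),
#'   `stimulus_ids`, `times`
#' @export
subaverage <- function(epochs, config, permutation_index = 1) {
  idx <- kept_experimental(epochs)
  ids <- epochs$trial_meta$stimulus_id[idx]
  stims <- sort(unique(ids))
  S <- config$n_splits
  d <- dim(epochs$data)
  n_t <- d[3L]; n_ch <- d[2L]
  counts <- table(ids)
  short <- names(counts)[counts < S]
  if (length(short))
    stop("stimulus ", paste(short, collapse = ", "), " has fewer than ",
         S, " retained trials")
  averages <- array(0, c(length(stims), S, n_ch, n_t))
  cnt <- matrix(0L, length(stims), S,
                dimnames = list(stims, NULL))
  with_seed(derive_seed(config$seed, permutation_index), {
    for (si in seq_along(stims)) {
      tr <- idx[ids == stims[si]]
      assign <- sample(rep_len(sample(S), length(tr)))
      for (sp in seq_len(S)) {
        sel <- tr[assign == sp]
        cnt[si, sp] <- length(sel)
        block <- epochs$data[sel, , , drop = FALSE]
        averages[si, sp, , ] <- colMeans(block, dims = 1)
      }
    }
  })
  structure(list(averages = averages, counts = cnt,
                 stimulus_ids = stims, times = epochs$times),
            class = "pseudo_trial_set")
}

#' Fit a multivariate noise normalizer (epoch method)
#'
#' Estimates the channel noise covariance from pseudo-trial residuals
#' (pseudo-trial minus its stimulus mean), per time point and averaged
#' over time points, shrinks it toward a scaled identity and returns
#' the symmetric inverse square root as the whitening matrix.
#'
#' @param train a `pseudo_trial_set` (training folds only), or a
#'   stimulus x split x channels x time array
#' @param shrinkage_mode `"auto"` for the analytic Ledoit-Wolf-style
#'   intensity, `"fixed"` to use `shrinkage`
#' @param shrinkage fixed intensity in [0, 1]
#' @return object of class `noise_normalizer`: `whitening_matrix`,
#'   `shrinkage`
#' @export
fit_noise_normalizer <- function(train, shrinkage_mode = c("auto", "fixed"),
                                 shrinkage = 0.1) {
  shrinkage_mode <- match.arg(shrinkage_mode)
  avg <- if (inherits(train, "pseudo_trial_set")) train$averages else train
  dm <- dim(avg)
  if (dm[2L] < 2) stop("need >= 2 pseudo-trials per stimulus to form residuals")
  stim_mean <- colMeans(aperm(avg, c(2, 1, 3, 4)))  # stim x ch x time
  resid <- avg - aperm(array(stim_mean, c(dm[1], dm[3], dm[4], dm[2])),
                       c(1, 4, 2, 3))
  # rows = (split, stimulus, time) observations, cols = channels
  X <- matrix(aperm(resid, c(2, 1, 4, 3)), ncol = dm[3L])
  df <- dm[1L] * (dm[2L] - 1) * dm[4L]
  S <- crossprod(X) / df
  p <- ncol(S)
  m <- mean(diag(S))
  if (shrinkage_mode == "auto") {
    n <- nrow(X)
    Sn <- crossprod(X) / n
    d2 <- sum((Sn - diag(m, p))^2)
    b2 <- (sum(rowSums(X^2)^2) / n - sum(Sn^2)) / n
    shrinkage <- if (d2 > 0) min(1, max(0, b2 / d2)) else 0
  }
  if (shrinkage < 0 || shrinkage > 1) stop("`shrinkage` must be in [0, 1]")
  sigma <- (1 - shrinkage) * S + shrinkage * diag(m, p)
  e <- eigen(sigma, symmetric = TRUE)
  if (min(e$values) <= 1e-12 * max(e$values))
    stop("shrunk covariance is (near-)singular; increase `shrinkage` ",
         "or use shrinkage_mode = \"auto\"")
  W <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  dimnames(W) <- NULL
  structure(list(whitening_matrix = W, shrinkage = shrinkage),
            class = "noise_normalizer")
}

# Apply a whitening matrix to the channel dimension of a
# channels x items x time cube (or channels x time matrix).
apply_whitening <- function(W, x) {
  dm <- dim(x)
  y <- W %*% matrix(x, nrow = dm[1L])
  dim(y) <- dm
  y
}

#' Decode one stimulus pair at one time point
#'
#' Reference implementation of the cross-validated pairwise decoding
#' dissimilarity: for each fold, one split is held out per stimulus as
#' test, a linear SVM is trained on the remaining splits using the
#' channel vector at `time_index` as features (after multivariate noise
#' normalization fitted on the training folds over all stimuli), and
#' both held-out pseudo-trials are scored.  Returns the mean accuracy
#' over folds.
#'
#' @param pseudo a `pseudo_trial_set`
#' @param stim_a,stim_b stimulus identifiers
#' @param time_index time sample index (1-based)
#' @param config a `decoding_config`
#' @return mean decoding accuracy in [0, 1]
#' @export
pairwise_decode <- function(pseudo, stim_a, stim_b, time_index, config) {
  ia <- match(stim_a, pseudo$stimulus_ids)
  ib <- match(stim_b, pseudo$stimulus_ids)
  if (is.na(ia) || is.na(ib))
    stop("unknown stimulus id(s): ",
         paste(c(stim_a, stim_b)[is.na(c(ia, ib))], collapse = ", "))
  S <- config$n_splits
  acc <- numeric(S)
  for (fold in seq_len(S)) {
    tr_sp <- setdiff(seq_len(S), fold)
    nn <- fit_noise_normalizer(
      pseudo$averages[, tr_sp, , , drop = FALSE],
      shrinkage_mode = config$shrinkage_mode,
      shrinkage = config$shrinkage)
    W <- nn$whitening_matrix
    feat <- function(si, sp) as.numeric(
      W %*% pseudo$averages[si, sp, , time_index])
    Xtr <- rbind(t(vapply(tr_sp, function(sp) feat(ia, sp),
                          numeric(nrow(W)))),
                 t(vapply(tr_sp, function(sp) feat(ib, sp),
                          numeric(nrow(W)))))
    y <- rep(c(1, -1), each = length(tr_sp))
    Xte <- rbind(feat(ia, fold), feat(ib, fold))
    fit <- svm_train_cpp(Xtr, y, Xte, config$svm_cost)
    dec <- fit$decision
    ca <- if (dec[1] > 0) 1 else if (dec[1] < 0) 0 else 0.5
    cb <- if (dec[2] < 0) 1 else if (dec[2] > 0) 0 else 0.5
    acc[fold] <- (ca + cb) / 2
  }
  mean(acc)
}

#' Build a time-resolved neural RDM series
#'
#' For every unordered stimulus pair and time point, the cross-validated
#' pairwise decoding accuracy is computed for each of
#' `config$n_permutations` random subaveraging draws and averaged,
#' yielding one symmetric stimulus x stimulus RDM per time point.
#'
#' @param epochs a preprocessed `epoch_array`
#' @param config a `decoding_config`
#' @param participant_id identifier stored with the series
#' @return object of class `neural_rdm_series`: `values` (time x
#'   stimulus x stimulus, diagonal `NA`), `times`, `stimulus_ids`,
#'   `participant_id`, `config`
#' @export
build_rdm_series <- function(epochs, config = decoding_config(),
                             participant_id = "P01") {
  S <- config$n_splits
  times <- epochs$times
  n_t <- length(times)
  first <- subaverage(epochs, config, 1L)
  stims <- first$stimulus_ids
  n_stim <- length(stims)
  if (n_stim < 2) stop("need at least 2 stimuli to decode")
  npairs <- n_stim * (n_stim - 1) / 2
  acc_sum <- matrix(0, npairs, n_t)
  for (perm in seq_len(config$n_permutations)) {
    pseudo <- if (perm == 1L) first else subaverage(epochs, config, perm)
    fold_sum <- matrix(0, npairs, n_t)
    for (fold in seq_len(S)) {
      tr_sp <- setdiff(seq_len(S), fold)
      train4 <- pseudo$averages[, tr_sp, , , drop = FALSE]
      nn <- fit_noise_normalizer(train4,
                                 shrinkage_mode = config$shrinkage_mode,
                                 shrinkage = config$shrinkage)
      W <- nn$whitening_matrix
      # channels x (split within stimulus) x time training cube
      train <- aperm(train4, c(3, 2, 1, 4))
      dim(train) <- c(dim(train)[1L], (S - 1) * n_stim, n_t)
      test <- aperm(pseudo$averages[, fold, , , drop = FALSE],
                    c(3, 1, 4, 2))
      dim(test) <- c(dim(test)[1L], n_stim, n_t)
      train <- apply_whitening(W, train)
      test <- apply_whitening(W, test)
      fold_sum <- fold_sum + decode_fold_cpp(train, test, S - 1L,
                                             config$svm_cost)
    }
    acc_sum <- acc_sum + fold_sum / S
  }
  accs <- acc_sum / config$n_permutations
  values <- array(NA_real_, c(n_t, n_stim, n_stim),
                  dimnames = list(NULL, stims, stims))
  lower <- which(lower.tri(matrix(0, n_stim, n_stim)))
  upper_t <- which(upper.tri(matrix(0, n_stim, n_stim)))
  for (t in seq_len(n_t)) {
    M <- matrix(NA_real_, n_stim, n_stim)
    M[lower] <- accs[, t]
    M <- pmax(M, t(M), na.rm = TRUE)
    diag(M) <- NA_real_
    values[t, , ] <- M
  }
  structure(list(values = values, times = times, stimulus_ids = stims,
                 participant_id = participant_id, config = config),
            class = "neural_rdm_series")
}

#' @export
print.neural_rdm_series <- function(x, ...) {
  cat("<neural_rdm_series> participant ", x$participant_id, ": ",
      length(x$stimulus_ids), " stimuli x ", length(x$times),
      " time points\n", sep = "")
  invisible(x)
}

#' Mean decoding time course
#'
#' Averages all pairwise decoding accuracies in the strict upper
#' triangle of the RDM (the diagonal is undefined and excluded) per
#' time point.
#'
#' @param series a `neural_rdm_series`
#' @return numeric vector, one mean accuracy per time point
#' @export
mean_decoding_timecourse <- function(series) {
  n <- length(series$stimulus_ids)
  ut <- upper.tri(matrix(0, n, n))
  vapply(seq_along(series$times), function(t)
    mean(series$values[t, , ][ut]), numeric(1))
}
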