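#' Epoched EEG container
#'
#' Holds a trials x channels x time array of amplitudes (microvolts)
#' together with the time axis (ms relative to stimulus onset), channel
#' labels and unit-sphere positions, a per-trial metadata table and the
#' current reference label.
#'
#' @param data numeric array, trials x channels x time
#' @param times numeric vector of sample times in ms (strictly
#'   increasing, uniform step)
#' @param channel_labels character vector, one label per channel
#' @param channel_positions numeric matrix channels x 3 of unit-sphere
#'   coordinates, or NULL to look labels up in [standard_montage()]
#' @param trial_meta data.frame with at least `stimulus_id`,
#'   `trial_type` and `keep_flag` columns, one row per trial
#' @param reference character scalar naming the current reference
#' @return an object of class `epoch_array`
#' @export
epoch_array <- function(data, times, channel_labels,
                        channel_positions = NULL, trial_meta,
                        reference = "recording") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (trials x channels x time)")
  d <- dim(data)
  if (length(times) != d[3L])
    stop("length(times) [", length(times), "] != time dimension [", d[3L], "]")
  dt <- diff(times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(abs(dt))))
    stop("`times` must be strictly increasing with a uniform step")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  if (length(channel_labels) != d[2L])
    stop("number of channel labels != channel dimension")
  if (is.null(channel_positions)) {
    pos <- standard_montage(channel_labels)
    channel_positions <- as.matrix(pos[, c("x", "y", "z")])
  }
  channel_positions <- as.matrix(channel_positions)
  if (nrow(channel_positions) != d[2L] || ncol(channel_positions) != 3L)
    stop("`channel_positions` must be channels x 3")
  if (!is.data.frame(trial_meta) || nrow(trial_meta) != d[1L])
    stop("`trial_meta` must be a data.frame with one row per trial")
  need <- c("stimulus_id", "trial_type", "keep_flag")
  miss <- setdiff(need, names(trial_meta))
  if (length(miss))
    stop("trial_meta lacks column(s): ", paste(miss, collapse = ", "))
  rownames(channel_positions) <- channel_labels
  structure(
    list(data = data, times = as.numeric(times),
         channel_labels = as.character(channel_labels),
         channel_positions = channel_positions,
         trial_meta = trial_meta, reference = reference),
    class = "epoch_array"
  )
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_array> ", d[1L], " trials x ", d[2L], " channels x ",
      d[3L], " samples\n", sep = "")
  cat("  time: ", min(x$times), "..", max(x$times), " ms, step ",
      diff(x$times[1:2]), " ms\n", sep = "")
  cat("  reference: ", x$reference, "; kept trials: ",
      sum(x$trial_meta$keep_flag), "/", d[1L], "\n", sep = "")
  invisible(x)
}

#' @export
dim.epoch_array <- function(x) dim(x$data)

# Sampling frequency in Hz implied by the time axis (ms).
epoch_sfreq <- function(epochs) 1000 / diff(epochs$times[1:2])

# Subset trials, keeping metadata aligned.
epoch_subset <- function(epochs, idx) {
  epochs$data <- epochs$data[idx, , , drop = FALSE]
  epochs$trial_meta <- epochs$trial_meta[idx, , drop = FALSE]
  rownames(epochs$trial_meta) <- NULL
  epochs
}

# Trials that enter analysis: experimental and not artifact-flagged.
kept_experimental <- function(epochs) {
  which(epochs$trial_meta$keep_flag &
          epochs$trial_meta$trial_type == "experimental")
}
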