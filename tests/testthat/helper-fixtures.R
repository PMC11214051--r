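# Shared fixture builders: everything is generated in code at test time.

# Minimal epoch array: trials x channels x time with labelled montage
# channels, experimental trials cycling through `stimuli`.
make_epochs <- function(n_stim = 4, n_rep = 10, n_ch = 8, n_t = 50,
                        sfreq = 100, data = NULL, seed = 1) {
  labels <- c(head(setdiff(standard_montage()$label, c("TP9", "TP10")),
                   n_ch - 2), "TP9", "TP10")
  stim <- sprintf("S%02d_a", seq_len(n_stim))
  n_trials <- n_stim * n_rep
  times <- seq(-100, by = 1000 / sfreq, length.out = n_t)
  if (is.null(data)) {
    set.seed(seed)
    data <- array(rnorm(n_trials * n_ch * n_t), c(n_trials, n_ch, n_t))
  }
  meta <- data.frame(stimulus_id = rep(stim, each = n_rep),
                     trial_type = "experimental", keep_flag = TRUE,
                     stringsAsFactors = FALSE)
  epoch_array(data, times, labels, trial_meta = meta)
}

# Tiny complete rating table from explicit per-stimulus values.
make_rating_table <- function(values, n_raters = 3, noise_sd = 0,
                              characteristic = "gender", seed = 1) {
  set.seed(seed)
  out <- expand.grid(rater_id = sprintf("R%02d", seq_len(n_raters)),
                     stimulus_id = names(values),
                     stringsAsFactors = FALSE)
  out$characteristic <- characteristic
  out$rating <- as.integer(pmin(9, pmax(1, round(
    values[out$stimulus_id] + rnorm(nrow(out), sd = noise_sd)))))
  structure(out[, c("rater_id", "stimulus_id", "characteristic", "rating")],
            class = c("rating_table", "data.frame"))
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m)), na.rm = TRUE), tol)
}
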