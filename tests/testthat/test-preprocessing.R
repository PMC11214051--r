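test_that("bad-channel detection flags a gross outlier channel and nothing else", {
  ep <- make_epochs(n_stim = 4, n_rep = 6, n_ch = 16, n_t = 100, seed = 2)
  qc0 <- detect_bad_channels(ep)
  expect_length(qc0$bad_channels, 0)
  # identical channels: nothing to flag
  flat <- ep
  for (ch in 2:16) flat$data[, ch, ] <- flat$data[, 1, ]
  expect_length(detect_bad_channels(flat)$bad_channels, 0)
  # one channel replaced by 10x-amplitude white noise
  set.seed(7)
  noisy <- ep
  noisy$data[, 5, ] <- 10 * rnorm(length(noisy$data[, 5, ]))
  qc <- detect_bad_channels(noisy)
  expect_identical(qc$bad_channels, ep$channel_labels[5])
  # an infinite threshold flags nothing
  expect_length(detect_bad_channels(noisy, threshold_sd = Inf)$bad_channels, 0)
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  ep <- make_epochs(n_stim = 2, n_rep = 2, n_ch = 16, n_t = 20, seed = 3)
  # constant field: reconstruction is exact to <1%
  const <- ep
  const$data[] <- 7
  out <- interpolate_channels(const, ep$channel_labels[3])
  expect_lt(max(abs(out$data[, 3, ] - 7)) / 7, 0.01)
  # field linear in the z coordinate: held-out channel within 5%
  lin <- ep
  z <- ep$channel_positions[, 3]
  for (ch in seq_along(z)) lin$data[, ch, ] <- 1 + z[ch]
  target <- 4L  # a central channel, well inside the cap
  out2 <- interpolate_channels(lin, ep$channel_labels[target])
  expect_lt(max(abs(out2$data[, target, ] - (1 + z[target]))) /
              abs(1 + z[target]), 0.05)
  # empty bad list is the identity
  expect_identical(interpolate_channels(ep, character(0)), ep)
  # good channels never change
  expect_equal(out$data[, -3, ], const$data[, -3, ])
})

test_that("amplitude rejection flags exactly the offending trial and never edits data", {
  ep <- make_epochs(n_stim = 2, n_rep = 4, n_ch = 6, n_t = 30, seed = 4)
  ep$data <- ep$data * 5  # ~35 uV peak-to-peak, below threshold
  clean <- reject_amplitude_artifacts(ep)
  expect_true(all(clean$trial_meta$keep_flag))
  zero <- ep; zero$data[] <- 0
  expect_true(all(reject_amplitude_artifacts(zero)$trial_meta$keep_flag))
  spiky <- ep
  spiky$data[3, 2, 10] <- spiky$data[3, 2, 10] + 200
  flagged <- reject_amplitude_artifacts(spiky)
  expect_identical(which(!flagged$trial_meta$keep_flag), 3L)
  expect_identical(flagged$data, spiky$data)  # pure flagging
  # zero threshold rejects every non-constant trial
  all_out <- reject_amplitude_artifacts(ep, peak_to_peak_uv = 0)
  expect_false(any(all_out$trial_meta$keep_flag))
})

test_that("band-pass filter has the specified pass/stop behavior with zero phase", {
  sfreq <- 1000
  n_t <- 801
  times <- seq(-100, 700)
  lab <- c("Cz", "TP9", "TP10")
  mk <- function(f) {
    x <- sin(2 * pi * f * times / 1000)
    arr <- array(rep(x, each = 3), c(1, 3, n_t))
    for (ch in 1:3) arr[1, ch, ] <- x
    epoch_array(arr, times, lab,
                trial_meta = data.frame(stimulus_id = "s", trial_type =
                  "experimental", keep_flag = TRUE))
  }
  filt10 <- bandpass_filter(mk(10), 0.1, 30, 4)
  mid <- times > 0 & times < 600
  gain10 <- sd(filt10$data[1, 1, mid]) / sd(mk(10)$data[1, 1, mid])
  expect_gt(gain10, 0.95); expect_lt(gain10, 1.005)
  # zero phase: peak positions unchanged
  lag <- which.max(ccf(filt10$data[1, 1, mid], mk(10)$data[1, 1, mid],
                       lag.max = 5, plot = FALSE)$acf) - 6
  expect_equal(lag, 0)
  filt100 <- bandpass_filter(mk(100), 0.1, 30, 4)
  expect_lt(sd(filt100$data[1, 1, mid]) / sd(mk(100)$data[1, 1, mid]), 0.05)
  z <- mk(10); z$data[] <- 0
  expect_equal(max(abs(bandpass_filter(z, 0.1, 30)$data)), 0)
  expect_error(bandpass_filter(mk(10), 40, 30), "invalid band")
  expect_error(bandpass_filter(mk(10), 0.1, 600), "Nyquist")
})

test_that("baseline correction zeroes the prestimulus mean", {
  ep <- make_epochs(n_stim = 2, n_rep = 3, n_ch = 6, n_t = 80, seed = 5)
  const <- ep; const$data[] <- 7
  out <- baseline_correct(const)
  expect_equal(max(abs(out$data)), 0)
  out2 <- baseline_correct(ep)
  sel <- ep$times >= -100 & ep$times <= 0
  base <- apply(out2$data[, , sel, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(base)), 1e-10)
  expect_error(baseline_correct(ep, c(-500, -400)), "no samples")
})

test_that("re-referencing subtracts the mean of the reference channels", {
  ep <- make_epochs(n_stim = 2, n_rep = 3, n_ch = 8, n_t = 40, seed = 6)
  refidx <- match(c("TP9", "TP10"), ep$channel_labels)
  zeroref <- ep
  zeroref$data[, refidx, ] <- 0
  expect_equal(rereference(zeroref)$data, zeroref$data)
  out <- rereference(ep)
  refmean <- apply(out$data[, refidx, , drop = FALSE], c(1, 3), mean)
  expect_lt(max(abs(refmean)), 1e-12)
  expect_equal(out$reference, "TP9+TP10")
  expect_error(rereference(ep, "M1"), "not found")
})

test_that("the full preprocessing chain runs, reports QC and is deterministic", {
  ep <- make_epochs(n_stim = 4, n_rep = 6, n_ch = 16, n_t = 80, seed = 7)
  # one movement-like artifact trial: a large deflection on every
  # channel, so no single channel looks spectrally deviant
  ep$data[10, , 40] <- ep$data[10, , 40] + 300
  out1 <- preprocess_epochs(ep, list(lowpass_pre_hz = NULL))
  out2 <- preprocess_epochs(ep, list(lowpass_pre_hz = NULL))
  expect_identical(out1$data, out2$data)
  qc <- attr(out1, "qc_report")
  expect_gte(qc$n_rejected_amplitude, 1)
  expect_false(out1$trial_meta$keep_flag[10])
  expect_equal(out1$reference, "TP9+TP10")
  expect_true(qc$pct_trials_rejected >= 100 / nrow(ep$trial_meta))
})
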