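test_that("acoustic generator: zero latent mixing decouples acoustics from traits", {
  # with no mixing, the acoustic dimensions are driven only by gender,
  # vowel and noise, which are independent of the latent trait space;
  # the rating-acoustics correlation should hover at chance
  rho <- sapply(1:25, function(seed) {
    st <- make_stimulus_set(16, c("a", "u"))
    sp <- generate_latent_space(16, 1, matrix(0.8, 1, 8),
                                uniqueness = 0.2, seed = seed)
    ac <- generate_acoustics(sp, st, seed = seed + 500, latent_mixing = 0)
    rt <- generate_ratings(sp, st, 10, include_noise_scale = FALSE,
                           seed = seed + 900)
    mr <- mean_ratings(rt, min_icc = 0)
    beh <- vectorize_rdm(rating_rdm(mr, "gender")$values)
    d1 <- ac$acoustic_scores[, 1]
    aco <- vectorize_rdm(abs(outer(d1, d1, "-")))
    cor(beh, aco, method = "spearman")
  })
  expect_lt(abs(mean(rho)), 0.05)
})

test_that("acoustic generator output is structurally valid and deterministic", {
  st <- make_stimulus_set(8, c("a", "u"))
  sp <- generate_latent_space(8, 2, seed = 4)
  ac1 <- generate_acoustics(sp, st, seed = 9)
  ac2 <- generate_acoustics(sp, st, seed = 9)
  expect_identical(ac1$features, ac2$features)
  expect_identical(ac1$ltas$spectra, ac2$ltas$spectra)
  meas <- voicersa:::measure_catalog()$name
  expect_true(all(meas %in% names(ac1$features)))
  expect_equal(length(meas), 13L)
  expect_true(all(ac1$ltas$spectra > 0))  # linear power is positive
  f <- ac1$features
  expect_true(all(f$F1 < f$F2 & f$F2 < f$F3 & f$F3 < f$F4))
  expect_true(all(f$F0_mean > 0))
})

test_that("feature PCA recovers a latent that is mixed into the acoustics", {
  # mixing only latent 1 into acoustic dimension 1, with the structured
  # gender/vowel drivers silenced, the leading feature component tracks
  # the latent
  st <- make_stimulus_set(24, "a")
  sp <- generate_latent_space(24, 1, matrix(0.8, 1, 8),
                              uniqueness = 0.2, seed = 21)
  ac <- generate_acoustics(sp, st, seed = 22,
                           latent_mixing = matrix(c(1, 0), 1, 2),
                           gender_weight = 0, vowel_weight = 0,
                           noise_weight = 0.1)
  pca <- pca_oblimin(as.matrix(ac$features[, voicersa:::measure_catalog()$name]))
  lat <- sp$latent_scores[match(st$speaker_id, unique(st$speaker_id)), 1]
  best <- max(abs(cor(pca$component_scores, lat)))
  expect_gt(best, 0.9)
})

test_that("EEG generator is bit-reproducible and respects the epoch window", {
  st <- make_stimulus_set(4, "a")
  d <- generate_design(st, 4, 0, 0, 1, seed = 1)
  sp <- generate_latent_space(4, 1, matrix(0.8, 1, 8), seed = 1)
  pat <- random_scalp_patterns(1, as.matrix(standard_montage()[, 2:4]),
                               seed = 2)
  tr <- synthetic_truth(cbind(100, 300), pat, snr = 1, seed = 1)
  e1 <- generate_eeg(d, sp, tr, sfreq = 100, seed = 5)
  e2 <- generate_eeg(d, sp, tr, sfreq = 100, seed = 5)
  expect_identical(e1$data, e2$data)
  bad <- synthetic_truth(cbind(100, 800), pat, snr = 1, seed = 1)
  expect_error(generate_eeg(d, sp, bad, sfreq = 100, seed = 5),
               "outside the epoch window")
})

test_that("trials of the same stimulus share the deterministic part", {
  st <- make_stimulus_set(4, "a")
  d <- generate_design(st, 6, 0, 0, 1, seed = 3)
  sp <- generate_latent_space(4, 1, matrix(0.8, 1, 8), seed = 3)
  pat <- random_scalp_patterns(1, as.matrix(standard_montage()[, 2:4]),
                               seed = 2)
  tr <- synthetic_truth(cbind(100, 300), pat, snr = 5, seed = 1)
  ep <- generate_eeg(d, sp, tr, sfreq = 100, seed = 8)
  # averaging trials of one stimulus converges on its deterministic
  # part; two averages of disjoint trial halves agree much better than
  # trial pairs do
  idx <- which(ep$trial_meta$stimulus_id == st$stimulus_id[1])
  h1 <- apply(ep$data[idx[1:3], , ], c(2, 3), mean)
  h2 <- apply(ep$data[idx[4:6], , ], c(2, 3), mean)
  inwin <- ep$times >= 100 & ep$times <= 300
  expect_gt(cor(as.vector(h1[, inwin]), as.vector(h2[, inwin])), 0.7)
})

test_that("the temporal kernel is flat mid-window and zero outside", {
  times <- seq(-100, 700, by = 10)
  k <- voicersa:::tukey_kernel(times, 100, 300, taper = 0.5)
  expect_true(all(k[times < 100 | times > 300] == 0))
  expect_true(all(k[times >= 150 & times <= 250] == 1))
  expect_true(all(k >= 0 & k <= 1))
  # taper = 1 is the raised-cosine limit: 0.5 at the quarter points
  k2 <- voicersa:::tukey_kernel(times, 100, 300, taper = 1)
  expect_equal(k2[times == 150], 0.5, tolerance = 1e-12)
  expect_equal(k2[times == 200], 1, tolerance = 1e-12)
})

test_that("noise has the intended spatial correlation between neighboring channels", {
  st <- make_stimulus_set(4, "a")
  d <- generate_design(st, 10, 0, 0, 1, seed = 2)
  sp <- generate_latent_space(4, 1, matrix(0.8, 1, 8), seed = 2)
  pat <- random_scalp_patterns(1, as.matrix(standard_montage()[, 2:4]),
                               seed = 2)
  tr <- synthetic_truth(cbind(100, 300), pat, snr = 0, seed = 1)
  ep <- generate_eeg(d, sp, tr, sfreq = 100, seed = 6)
  pos <- ep$channel_positions
  dmat <- voicersa:::angular_distance(pos)
  diag(dmat) <- Inf
  nb <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
  x <- as.vector(ep$data[, nb[1], ])
  y <- as.vector(ep$data[, nb[2], ])
  expect_gt(cor(x, y), 0.45)
  expect_lt(cor(x, y), 0.75)
})
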