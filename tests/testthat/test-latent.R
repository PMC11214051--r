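test_that("latent scores are exactly standardized and correlations follow in closed form", {
  sp <- generate_latent_space(32, 2, seed = 5)
  expect_equal(colMeans(sp$latent_scores), c(latent1 = 0, latent2 = 0),
               tolerance = 1e-12)
  expect_equal(apply(sp$latent_scores, 2, sd),
               c(latent1 = 1, latent2 = 1), tolerance = 1e-12)
  # identity-style loadings, zero uniqueness: characteristic
  # correlations equal the latent correlations (here: identity blocks)
  L <- matrix(0, 2, 8)
  L[1, 1:4] <- 1; L[2, 5:8] <- 1
  sp2 <- generate_latent_space(16, 2, L, uniqueness = 0, seed = 1)
  expect_equal(unname(sp2$implied_correlation[1, 2]), 1)
  expect_equal(unname(sp2$implied_correlation[1, 5]), 0)
  # single shared latent, zero uniqueness: all correlations are 1
  L1 <- matrix(1, 1, 8)
  sp3 <- generate_latent_space(16, 1, L1, uniqueness = 0, seed = 1)
  expect_true(all(abs(sp3$implied_correlation - 1) < 1e-12))
})

test_that("empirical rating correlations track the closed-form implied matrix", {
  L <- rbind(c(0.9, 0.8, 0.7, 0.1, 0, 0, 0.2, 0.1),
             c(0.1, 0, 0.2, 0.9, 0.85, 0.8, 0.3, 0.2))
  sp <- generate_latent_space(32, 2, L, uniqueness = 0.3, seed = 7)
  st <- make_stimulus_set(32)
  rt <- generate_ratings(sp, st, n_raters = 20, rater_noise_sd = 0.5,
                         stimulus_jitter_sd = 0.05,
                         include_noise_scale = FALSE, seed = 7)
  mr <- mean_ratings(rt, min_icc = 0)
  emp <- cor(mr$values[, colnames(sp$implied_correlation)])
  # Monte-Carlo agreement at 32 speakers x 20 raters: sampling error of
  # a correlation at n = 32 is ~0.17 at worst, so compare on average
  # and cap the worst single entry
  dev <- abs(emp - sp$implied_correlation)
  expect_lt(mean(dev[upper.tri(dev)]), 0.08)
  expect_lt(max(dev), 0.25)
})

test_that("ratings are integers in 1..9; zero noise gives identical raters and ICC2k of 1", {
  sp <- generate_latent_space(8, 1, matrix(0.8, 1, 8), uniqueness = 0.2,
                              seed = 3)
  st <- make_stimulus_set(8, c("a", "u"))
  rt <- generate_ratings(sp, st, n_raters = 4, rater_noise_sd = 0,
                         include_noise_scale = FALSE, seed = 3)
  expect_true(all(rt$rating %in% 1:9))
  m <- voicersa:::rating_matrix(rt[rt$characteristic == "gender", ])
  expect_true(all(m == m[, 1]))
  expect_equal(unname(icc2k(m)), 1, tolerance = 1e-12)
})

test_that("extreme latent values are clipped at the scale bounds", {
  # two standardized speakers sit at z = +/-1; a loading of 10 pushes
  # both far outside the scale
  sp <- generate_latent_space(2, 1, matrix(10, 1, 8), uniqueness = 0,
                              seed = 2)
  st <- make_stimulus_set(2, "a")
  rt <- generate_ratings(sp, st, n_raters = 2, rater_noise_sd = 0,
                         include_noise_scale = FALSE, seed = 2)
  expect_true(all(rt$rating %in% c(1L, 9L)))
})

test_that("ICC2k of generated ratings falls in a precomputed Monte-Carlo band", {
  # band frozen from 200 replicates of this exact configuration
  # (8 speakers x 2 vowels, 10 raters, noise 1.5): 2.5-97.5 percentiles
  # of ICC2k were [0.733, 0.927]; test three fresh seeds inside a
  # slightly widened band
  for (seed in c(101, 202, 303)) {
    sp <- generate_latent_space(8, 1, matrix(0.8, 1, 8),
                                uniqueness = 0.3, seed = seed)
    st <- make_stimulus_set(8, c("a", "u"))
    rt <- generate_ratings(sp, st, n_raters = 10, rater_noise_sd = 1.5,
                           include_noise_scale = FALSE, seed = seed)
    m <- voicersa:::rating_matrix(rt[rt$characteristic == "gender", ])
    expect_gt(icc2k(m), 0.68)
    expect_lt(icc2k(m), 0.95)
  }
})

test_that("the optional ninth scale has near-zero agreement and is screened out", {
  sp <- generate_latent_space(8, 1, matrix(0.8, 1, 8), uniqueness = 0.3,
                              seed = 11)
  st <- make_stimulus_set(8, c("a", "u"))
  rt <- generate_ratings(sp, st, n_raters = 15, rater_noise_sd = 1.5,
                         include_noise_scale = TRUE, seed = 11)
  mr <- mean_ratings(rt)
  expect_true("sexual_orientation" %in% mr$dropped_characteristics)
  expect_false("sexual_orientation" %in% colnames(mr$values))
})
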