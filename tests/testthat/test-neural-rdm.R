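test_that("subaverage balances splits, averages correctly and is reproducible", {
  ep <- make_epochs(n_stim = 3, n_rep = 10, n_ch = 6, n_t = 20, seed = 1)
  cfg <- decoding_config(n_splits = 5, n_permutations = 2, seed = 42)
  ps <- subaverage(ep, cfg, 1)
  expect_equal(dim(ps$averages), c(3, 5, 6, 20))
  expect_true(all(ps$counts == 2))  # 10 trials over 5 splits
  # pseudo-trial equals the brute-force mean of its split's trials
  grand <- apply(ep$data[ep$trial_meta$stimulus_id ==
                           ps$stimulus_ids[1], , , drop = FALSE],
                 c(2, 3), mean)
  recon <- apply(ps$averages[1, , , ] *
                   array(ps$counts[1, ], c(5, 6, 20)), c(2, 3), sum) /
    sum(ps$counts[1, ])
  expect_equal(recon, grand, tolerance = 1e-12)
  # determinism in (seed, permutation index)
  expect_identical(ps$averages, subaverage(ep, cfg, 1)$averages)
  expect_false(identical(ps$averages, subaverage(ep, cfg, 2)$averages))
  # identical trials give identical pseudo-trials
  flat <- ep; for (tr in seq_len(dim(flat$data)[1]))
    flat$data[tr, , ] <- flat$data[1, , ]
  pf <- subaverage(flat, cfg, 1)
  expect_equal(pf$averages[1, 1, , ], pf$averages[1, 5, , ],
               tolerance = 1e-12)
  # too few retained trials errors, naming the stimulus
  small <- ep
  drop_idx <- which(small$trial_meta$stimulus_id == ps$stimulus_ids[2])[1:7]
  small$trial_meta$keep_flag[drop_idx] <- FALSE
  expect_error(subaverage(small, cfg, 1), ps$stimulus_ids[2])
})

test_that("noise normalizer matches closed forms and whitens exactly at zero shrinkage", {
  # build pseudo-trials with residual covariance = diag(4, 1, 1, 1)
  set.seed(10)
  n_stim <- 20; n_split <- 4; n_ch <- 4; n_t <- 10
  sds <- c(2, 1, 1, 1)
  avg <- array(0, c(n_stim, n_split, n_ch, n_t))
  for (s in seq_len(n_stim)) for (ch in seq_len(n_ch))
    avg[s, , ch, ] <- rnorm(n_split * n_t, sd = sds[ch])
  nn <- fit_noise_normalizer(avg, shrinkage_mode = "fixed", shrinkage = 0)
  W <- nn$whitening_matrix
  expect_symmetric(W)
  # channel 1 scaled by ~1/2 relative to the others
  expect_equal(W[1, 1] / W[2, 2], 0.5, tolerance = 0.1)
  # algebraic check: W %*% Sigma %*% W == identity at shrinkage 0
  resid <- avg - aperm(array(apply(avg, c(1, 3, 4), mean),
                             c(n_stim, n_ch, n_t, n_split)), c(1, 4, 2, 3))
  X <- matrix(aperm(resid, c(2, 1, 4, 3)), ncol = n_ch)
  Sig <- crossprod(X) / (n_stim * (n_split - 1) * n_t)
  expect_lt(max(abs(W %*% Sig %*% W - diag(n_ch))), 1e-8)
  # identity residual covariance: whitening is the identity (up to
  # sampling error, exactly so when fed the true covariance route)
  nn_id <- fit_noise_normalizer(avg * 0 +
    array(rnorm(length(avg)), dim(avg)), shrinkage_mode = "fixed",
    shrinkage = 1)
  expect_lt(max(abs(nn_id$whitening_matrix -
                      diag(diag(nn_id$whitening_matrix)))), 1e-12)
})

test_that("degenerate residuals error at zero shrinkage with advice", {
  avg <- array(0, c(2, 2, 3, 2))  # all-zero residuals
  expect_error(fit_noise_normalizer(avg, "fixed", 0), "shrinkage")
})

test_that("pairwise decoding is symmetric, calibrated at chance and perfect when separable", {
  ep <- make_epochs(n_stim = 2, n_rep = 20, n_ch = 8, n_t = 5, seed = 2)
  cfg <- decoding_config(n_splits = 5, n_permutations = 1, seed = 3)
  ids <- unique(ep$trial_meta$stimulus_id)
  # identical class distributions: accuracy near 0.5 averaged over draws
  accs <- sapply(1:20, function(p) {
    ps <- subaverage(ep, cfg, p)
    pairwise_decode(ps, ids[1], ids[2], 3, cfg)
  })
  expect_gt(mean(accs), 0.35); expect_lt(mean(accs), 0.65)
  # label symmetry
  ps <- subaverage(ep, cfg, 1)
  expect_equal(pairwise_decode(ps, ids[1], ids[2], 2, cfg),
               pairwise_decode(ps, ids[2], ids[1], 2, cfg))
  # means separated by 10 noise SDs decode perfectly
  sep <- ep
  sel <- sep$trial_meta$stimulus_id == ids[2]
  sep$data[sel, , ] <- sep$data[sel, , ] + 10
  ps_sep <- subaverage(sep, cfg, 1)
  expect_equal(pairwise_decode(ps_sep, ids[1], ids[2], 3, cfg), 1.0)
})

test_that("the in-package SVM agrees with libsvm (e1071) on random problems", {
  skip_if_not_installed("e1071")
  agree <- 0L; total <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 6), 8)
    y <- rep(c(1, -1), each = 4)
    Xt <- matrix(rnorm(6 * 6), 6)
    mine <- sign(voicersa:::svm_train_cpp(X, y, Xt, 1)$decision)
    ref <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                      cost = 1, scale = FALSE)
    dv <- attr(predict(ref, Xt, decision.values = TRUE),
               "decision.values")
    keep <- abs(dv) > 1e-3  # ignore ties at the margin
    agree <- agree + sum(mine[keep] == sign(as.numeric(dv))[keep])
    total <- total + sum(keep)
  }
  expect_gte(agree / total, 0.99)
})

test_that("RDM series are symmetric, deterministic, and agree with the reference path", {
  ep <- make_epochs(n_stim = 4, n_rep = 10, n_ch = 8, n_t = 6, seed = 5)
  cfg <- decoding_config(n_splits = 5, n_permutations = 2, seed = 7)
  rdm <- build_rdm_series(ep, cfg)
  for (t in seq_along(rdm$times)) {
    expect_symmetric(rdm$values[t, , ])
    expect_true(all(is.na(diag(rdm$values[t, , ]))))
  }
  expect_identical(rdm$values, build_rdm_series(ep, cfg)$values)
  # the fast fold loop equals the per-pair reference implementation
  ps <- subaverage(ep, cfg, 1)
  ids <- ps$stimulus_ids
  t_idx <- 3L
  ref_acc <- pairwise_decode(ps, ids[1], ids[3], t_idx, cfg)
  one_perm <- decoding_config(n_splits = 5, n_permutations = 1, seed = 7)
  rdm1 <- build_rdm_series(ep, one_perm)
  expect_equal(rdm1$values[t_idx, ids[1], ids[3]], ref_acc,
               tolerance = 1e-12)
})

test_that("planted two-cluster geometry separates between from within", {
  ep <- make_epochs(n_stim = 4, n_rep = 10, n_ch = 8, n_t = 4, seed = 6)
  ids <- unique(ep$trial_meta$stimulus_id)
  grp2 <- ep$trial_meta$stimulus_id %in% ids[3:4]
  ep$data[grp2, 1:4, ] <- ep$data[grp2, 1:4, ] + 3
  cfg <- decoding_config(n_splits = 5, n_permutations = 3, seed = 8)
  rdm <- build_rdm_series(ep, cfg)
  v <- rdm$values[2, , ]
  between <- v[ids[1:2], ids[3:4]]
  within <- c(v[ids[1], ids[2]], v[ids[3], ids[4]])
  expect_gt(mean(between), mean(within))
  expect_gt(mean(between), 0.9)
})

test_that("the mean decoding time course averages the strict upper triangle", {
  ep <- make_epochs(n_stim = 4, n_rep = 10, n_ch = 4, n_t = 3, seed = 9)
  cfg <- decoding_config(n_splits = 5, n_permutations = 1, seed = 2)
  rdm <- build_rdm_series(ep, cfg)
  # hand-build a series with one pair at 1.0, the rest at 0.5
  rdm$values[] <- 0.5
  rdm$values[2, 1, 2] <- rdm$values[2, 2, 1] <- 1.0
  for (t in 1:3) diag(rdm$values[t, , ]) <- NA
  mt <- mean_decoding_timecourse(rdm)
  expect_equal(mt[1], 0.5)
  expect_equal(mt[2], (5 * 0.5 + 1) / 6)
})
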