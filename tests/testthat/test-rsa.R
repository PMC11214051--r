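test_that("RDM vectorization order, length and symmetry checks", {
  m <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  expect_equal(vectorize_rdm(m), c(1, 2, 3))
  expect_equal(vectorize_rdm(t(m)), vectorize_rdm(m))
  big <- matrix(0, 96, 96)
  expect_length(vectorize_rdm(big), 4560)
  asym <- m; asym[1, 2] <- 9
  expect_error(vectorize_rdm(asym), "asymmetric")
  nadiag <- m; diag(nadiag) <- NA
  expect_equal(vectorize_rdm(nadiag), c(1, 2, 3))
})

test_that("partial Spearman equals the recursive closed form with one covariate", {
  set.seed(40)
  for (i in 1:100) {
    n <- 30
    x <- rnorm(n); y <- rnorm(n); z <- rnorm(n)
    rxy <- cor(x, y, method = "spearman")
    rxz <- cor(x, z, method = "spearman")
    ryz <- cor(y, z, method = "spearman")
    oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(spearman_partial(x, y, list(z)), oracle,
                 tolerance = 1e-12)
  }
})

test_that("partial Spearman reduces to Spearman, is monotone-invariant, flags degeneracies", {
  set.seed(41)
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(spearman_partial(x, y), cor(x, y, method = "spearman"),
               tolerance = 1e-12)
  expect_equal(spearman_partial(x, x), 1.0)
  # strictly monotone transforms of x and y leave the statistic alone
  z <- list(rnorm(25))
  expect_equal(spearman_partial(exp(x), y^3 + 5 * y, z),
               spearman_partial(x, y, z), tolerance = 1e-12)
  # covariate identical to x: undefined, not a number
  expect_true(is.na(spearman_partial(x, y, list(x))))
  expect_true(is.na(spearman_partial(rep(1, 25), y)))
  expect_error(spearman_partial(x, y[1:10], list()), "equal length")
  expect_error(spearman_partial(x[1:4], y[1:4], list(rnorm(4))),
               "at least")
})

test_that("run_model gives rho 1 against itself and honours item ordering", {
  ep <- make_epochs(n_stim = 5, n_rep = 10, n_ch = 6, n_t = 4, seed = 42)
  cfg <- decoding_config(n_splits = 5, n_permutations = 1, seed = 1)
  rdm <- build_rdm_series(ep, cfg)
  tgt <- rdm$values[2, , ]
  diag(tgt) <- 0
  tc <- run_model(rdm, tgt)
  expect_equal(tc$rho[2], 1.0)
  expect_true(all(tc$rho >= -1 & tc$rho <= 1, na.rm = TRUE))
  # mismatched item ordering is refused before computation
  shuffled <- tgt[c(2, 1, 3, 4, 5), c(2, 1, 3, 4, 5)]
  expect_error(run_model(rdm, shuffled), "ordering")
  # covariate equal to the target leaves every time point undefined
  tc2 <- run_model(rdm, tgt, covariates = list(tgt))
  expect_true(all(is.na(tc2$rho)))
})

test_that("null simulation: rho against an unrelated target is centred on zero", {
  set.seed(43)
  rhos <- sapply(1:60, function(i) {
    n <- 12
    a <- rnorm(n)
    nz <- matrix(rnorm(n * n, sd = 0.2), n)
    v <- abs(outer(a, a, "-")) + (nz + t(nz)) / 2
    diag(v) <- 0
    neural <- list(values = array(v, c(1, n, n)), times = 0,
                   stimulus_ids = as.character(seq_len(n)),
                   participant_id = "P")
    class(neural) <- "neural_rdm_series"
    b <- rnorm(n)
    tgt <- abs(outer(b, b, "-"))
    run_model(neural, tgt)$rho[1]
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("run_all_models builds the nested covariate sets", {
  ep <- make_epochs(n_stim = 6, n_rep = 10, n_ch = 6, n_t = 3, seed = 44)
  cfg <- decoding_config(n_splits = 5, n_permutations = 1, seed = 2)
  rdm <- build_rdm_series(ep, cfg)
  ids <- rdm$stimulus_ids
  set.seed(45)
  mk_rdm <- function() {
    v <- rnorm(6)
    m <- abs(outer(v, v, "-")); dimnames(m) <- list(ids, ids); m
  }
  beh <- list(gender = mk_rdm(), age = mk_rdm(), health = mk_rdm())
  aco <- structure(list(ltas_rdm = mk_rdm(),
                        pc_rdms = list(PC1 = mk_rdm(), PC2 = mk_rdm())),
                   class = "acoustic_rdm_set")
  out <- run_all_models(list(rdm), beh, aco,
                        models = c("M0", "M1", "M2", "M3"))
  expect_setequal(unique(out$model), c("M0", "M1", "M2", "M3"))
  expect_setequal(unique(out$characteristic), names(beh))
  expect_equal(nrow(out), 4 * 3 * length(rdm$times))
  m <- timecourse_matrix(out, "gender", "M1")
  expect_equal(dim(m), c(1, 3))
  # shuffling items identically everywhere leaves rho unchanged
  perm <- c(3, 1, 2, 6, 5, 4)
  shuffle <- function(m) m[perm, perm]
  rdm2 <- rdm; rdm2$values <- rdm$values[, perm, perm]
  rdm2$stimulus_ids <- ids[perm]
  out2 <- run_all_models(list(rdm2), lapply(beh, shuffle),
                         structure(list(ltas_rdm = shuffle(aco$ltas_rdm),
                                        pc_rdms = lapply(aco$pc_rdms, shuffle)),
                                   class = "acoustic_rdm_set"),
                        models = "M3")
  expect_equal(out2$rho[out2$characteristic == "gender"],
               out$rho[out$characteristic == "gender" & out$model == "M3"],
               tolerance = 1e-12)
})
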