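test_that("rater screening uses the modal-response fraction with a strict threshold", {
  vals <- setNames(rep(5, 10), sprintf("s%02d", 1:10))
  rt <- make_rating_table(vals, n_raters = 1)  # rater always answers 5
  rep_ <- screen_raters(rt)
  expect_equal(nrow(rep_$excluded), 1)
  expect_equal(rep_$max_same_fraction$max_same_fraction, 1.0)
  # a fraction of exactly 0.8 is retained (strict inequality)
  vals2 <- setNames(c(rep(5, 8), 4, 6), sprintf("s%02d", 1:10))
  rt2 <- make_rating_table(vals2, n_raters = 1)
  expect_equal(nrow(screen_raters(rt2)$excluded), 0)
  # a uniform-random rater stays comfortably below the threshold
  set.seed(1)
  frac <- replicate(200, max(table(sample(1:9, 96, TRUE))) / 96)
  expect_true(all(frac < 0.8))
})

test_that("icc2k equals an independent aov()-based variance decomposition", {
  set.seed(42)
  icc_oracle <- function(m) {
    df <- data.frame(y = as.vector(m),
                     item = factor(rep(seq_len(nrow(m)), ncol(m))),
                     rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
    ms <- summary(aov(y ~ item + rater, data = df))[[1]][, "Mean Sq"]
    (ms[1] - ms[3]) / (ms[1] + (ms[2] - ms[3]) / nrow(m))
  }
  for (i in 1:10) {
    m <- matrix(sample(1:9, 48, TRUE), 8, 6)
    if (sd(m) == 0) next
    expect_equal(icc2k(m), icc_oracle(m), tolerance = 1e-10)
  }
  # identical raters rating varying items -> 1
  m1 <- matrix(rep(1:6, 3), 6, 3)
  expect_equal(unname(icc2k(m1)), 1)
  # items all equal, raters differ -> non-positive
  m2 <- matrix(rep(c(2, 5, 8), each = 4), 4, 3)
  expect_lte(icc2k(m2), 0)
  # fully degenerate table is flagged undefined, not silent NaN
  m3 <- matrix(5, 4, 3)
  expect_true(is.na(icc2k(m3)))
  expect_true(isTRUE(attr(icc2k(m3), "undefined")))
})

test_that("mean ratings average retained raters per characteristic", {
  vals <- setNames(c(2, 5, 8), c("a", "b", "c"))
  rt <- make_rating_table(vals, n_raters = 2)
  rt$rating[rt$rater_id == "R02"] <- rt$rating[rt$rater_id == "R02"] + 1L
  mr <- mean_ratings(rt, min_icc = 0)
  expect_equal(unname(mr$values[, "gender"]), c(2.5, 5.5, 8.5))
  expect_equal(unname(mr$n_raters_used["gender"]), 2L)
  # a single retained rater reproduces that rater's ratings
  one <- rt[rt$rater_id == "R01", ]
  mr1 <- mean_ratings(one, min_icc = -Inf,
                      screen = screen_raters(one, max_same_fraction = 1))
  expect_equal(unname(mr1$values[, "gender"]), c(2, 5, 8))
})

test_that("characteristic correlations are Spearman correlations over stimuli", {
  set.seed(3)
  vals <- matrix(runif(96 * 8, 1, 9), 96, 8,
                 dimnames = list(sprintf("s%02d", 1:96), paste0("c", 1:8)))
  got <- characteristic_correlations(vals)
  oracle <- cor(apply(vals, 2, rank))  # rank-then-Pearson
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  expect_symmetric(got)
  # duplicated column correlates at 1; monotone transforms are invisible
  vals2 <- cbind(vals, dup = vals[, 1], mono = qnorm(vals[, 1] / 10))
  got2 <- characteristic_correlations(vals2)
  expect_equal(unname(got2["c1", "dup"]), 1)
  expect_equal(unname(got2["c1", "mono"]), 1)
  # constant column flagged undefined
  vals3 <- cbind(vals, k = 5)
  expect_true(is.na(characteristic_correlations(vals3)["c1", "k"]))
})

test_that("rating RDMs are absolute mean differences with metric structure", {
  vals <- setNames(c(1, 9, 4, 6), c("a", "b", "c", "d"))
  rt <- make_rating_table(vals, n_raters = 2)
  mr <- mean_ratings(rt, min_icc = 0)
  rdm <- rating_rdm(mr, "gender")
  expect_equal(unname(rdm$values["a", "b"]), 8)  # scale maximum
  expect_equal(unname(rdm$values["c", "d"]), 2)
  expect_symmetric(rdm$values)
  expect_true(all(diag(rdm$values) == 0))
  # triangle inequality holds for 1-d absolute distances
  set.seed(8)
  for (rep_ in 1:5) {
    v <- runif(6, 1, 9)
    D <- abs(outer(v, v, "-"))
    for (i in 1:6) for (j in 1:6) for (k in 1:6)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
  expect_error(rating_rdm(mr, "notachar"), "not among")
})
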