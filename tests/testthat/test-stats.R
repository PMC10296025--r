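trials_from <- function(gen, n_subj = 6, nmin = 5, nmax = 15) {
  out <- list()
  for (s in seq_len(n_subj)) out[[as.character(s)]] <- gen(sample(nmin:nmax, 1))
  out
}

test_that("identical trial sets give a zero observed statistic and p near 1", {
  set.seed(1)
  a <- trials_from(function(n) rnorm(n))
  pr <- permutation_test(a, a, n_perm = 200, seed = 2)
  expect_equal(pr$ground_truth, 0)
  expect_gt(pr$p_value, 0.5)
  expect_length(pr$null_distribution, 200)
})

test_that("p-values are add-one bounded, symmetric in condition order", {
  set.seed(2)
  a <- trials_from(function(n) rnorm(n, 0.5))
  b <- trials_from(function(n) rnorm(n))
  p_ab <- permutation_test(a, b, n_perm = 2000, seed = 7)
  p_ba <- permutation_test(b, a, n_perm = 2000, seed = 7)
  expect_gt(p_ab$p_value, 0)
  expect_lte(p_ab$p_value, 1)
  expect_equal(p_ab$ground_truth, -p_ba$ground_truth)
  # |null| has the same law either way; realizations differ by MC noise only
  expect_lt(abs(p_ab$p_value - p_ba$p_value), 0.05)
  # the (1+k)/(1+n) estimator can never return zero
  big <- lapply(1:5, function(i) rnorm(10, 100)); names(big) <- 1:5
  small <- lapply(1:5, function(i) rnorm(10)); names(small) <- 1:5
  expect_gte(permutation_test(big, small, n_perm = 100, seed = 1)$p_value,
             1 / 101)
})

test_that("subjects missing a condition are named in the error", {
  a <- list(`1` = rnorm(5), `2` = rnorm(5))
  b <- list(`1` = rnorm(5), `2` = numeric(0))
  expect_error(permutation_test(a, b, n_perm = 100), "2")
  expect_error(permutation_test(a, list(`1` = rnorm(5), `3` = rnorm(5)),
                                n_perm = 100), "subjects differ")
  expect_error(permutation_test(a, a, n_perm = 50), "100")
})

test_that("a 3-SD planted shift is detected with high power", {
  set.seed(3)
  reject <- vapply(1:20, function(i) {
    a <- lapply(1:20, function(s) rnorm(20, 3)); names(a) <- 1:20
    b <- lapply(1:20, function(s) rnorm(20, 0)); names(b) <- 1:20
    permutation_test(a, b, n_perm = 1000, seed = i)$p_value < 0.001
  }, TRUE)
  expect_gte(mean(reject), 0.95)
})

test_that("permutation counts only shift p within Monte-Carlo tolerance", {
  set.seed(4)
  a <- trials_from(function(n) rnorm(n, 0.4), n_subj = 10)
  b <- trials_from(function(n) rnorm(n), n_subj = 10)
  p100 <- permutation_test(a, b, n_perm = 100, seed = 5)
  p1000 <- permutation_test(a, b, n_perm = 1000, seed = 5)
  expect_equal(sign(p100$ground_truth), sign(p1000$ground_truth))
  expect_lt(abs(p100$p_value - p1000$p_value),
            3 * sqrt(p1000$p_value * (1 - p1000$p_value) / 100) + 0.02)
})

test_that("under exchangeability the p-value distribution is not anti-conservative", {
  set.seed(6)
  ps <- vapply(1:150, function(i) {
    a <- trials_from(function(n) rnorm(n), n_subj = 8)
    b <- trials_from(function(n) rnorm(n), n_subj = 8)
    permutation_test(a, b, n_perm = 199, seed = i)$p_value
  }, 0)
  expect_lt(mean(ps <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / 150))
})

test_that("Bonferroni uses the exact threshold with a strict inequality", {
  out <- bonferroni(c(0.0001, 0.0015625, 0.002), family_size = 32)
  expect_equal(out$threshold, 0.0015625)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))  # boundary: not sig.
  expect_equal(bonferroni(0.04, family_size = 1)$threshold, 0.05)
  expect_true(bonferroni(0.04, family_size = 1)$significant)
})

test_that("contrast_report aggregates features and handles empty input", {
  empty <- contrast_report(list())
  expect_equal(nrow(empty), 0)
  set.seed(8)
  mk_cond <- function(shift) {
    out <- lapply(1:8, function(s) rnorm(12, shift)); names(out) <- 1:8; out
  }
  feats <- list(
    shifted = list(planned = mk_cond(1.5), unplanned = mk_cond(0)),
    null = list(planned = mk_cond(0), unplanned = mk_cond(0)))
  rep <- contrast_report(feats, n_perm = 500, seed = 9)
  expect_equal(rep$feature, c("shifted", "null"))
  expect_true(rep$significant[1])
  expect_false(rep$significant[2])
  expect_gt(rep$observed[1], 1)
})
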