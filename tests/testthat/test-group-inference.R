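test_that("correlation Bayes factors match an independent trapezoid oracle", {
  for (r in c(-0.6, -0.2, 0.12, 0.42, 0.8)) {
    for (n in c(10, 36, 100)) {
      bf <- bf_correlation(r, n)
      expect_equal(bf$bf, oracle_bf_correlation(r, n), tolerance = 5e-4)
      expect_lt(bf$numerical_error, 1e-3)
    }
  }
  bf_pos <- bf_correlation(0.42, 36, side = "positive")
  expect_equal(bf_pos$bf, oracle_bf_correlation(0.42, 36, "positive"),
               tolerance = 5e-4)
})

test_that("one-sided correlation Bayes factors cohere with the two-sided one", {
  # for the symmetric width-1 prior, the two-sided BF is the arithmetic mean
  # of the positive- and negative-sided ones
  for (r in c(-0.3, 0.12, 0.55)) {
    two <- bf_correlation(r, 36)$bf
    pos <- bf_correlation(r, 36, side = "positive")$bf
    neg <- bf_correlation(r, 36, side = "negative")$bf
    expect_equal((pos + neg) / 2, two, tolerance = 1e-6)
  }
})

test_that("the positive-sided correlation BF is strictly increasing in r", {
  bfs <- vapply(seq(-0.5, 0.7, by = 0.1),
                function(r) bf_correlation(r, 36, side = "positive")$bf,
                numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("correlation BF inputs are validated", {
  expect_error(bf_correlation(1, 36), "< 1")
  expect_error(bf_correlation(0.3, 3), "n")
  expect_error(bf_correlation(0.3, 36, kappa = 0), "kappa")
})

test_that("JZS paired t-test BF matches quadrature and is monotone in |t|", {
  expect_equal(bf_ttest_paired(t = 5, n = 36)$bf, oracle_bf_ttest(5, 36),
               tolerance = 1e-4)
  expect_equal(bf_ttest_paired(t = 1.8, n = 24)$bf, oracle_bf_ttest(1.8, 24),
               tolerance = 1e-4)
  expect_lt(bf_ttest_paired(t = 0, n = 36)$bf, 1)   # null-favoured at t = 0
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 5),
                function(t) bf_ttest_paired(t = t, n = 36)$bf, numeric(1))
  expect_true(all(diff(bfs) > 0))
  # raw differences route computes t internally
  set.seed(8)
  d <- rnorm(30, 0.5)
  t_manual <- mean(d) / (sd(d) / sqrt(30))
  expect_equal(bf_ttest_paired(diffs = d)$bf,
               bf_ttest_paired(t = t_manual, n = 30)$bf, tolerance = 1e-8)
  expect_error(bf_ttest_paired(diffs = rep(1, 10)), "variance")
})

test_that("Steiger's Z reproduces hand-checked values and symmetries", {
  st <- steiger_overlapping(0.42, -0.04, 0.12, 36)
  expect_equal(st$z, 2.0907, tolerance = 1e-4)
  expect_equal(st$p, 2 * pnorm(-abs(st$z)), tolerance = 1e-12)
  # equal correlations: Z = 0, p = 1
  eq <- steiger_overlapping(0.3, 0.3, 0.1, 36)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # swapping the compared correlations negates Z
  sw <- steiger_overlapping(-0.04, 0.42, 0.12, 36)
  expect_equal(sw$z, -st$z, tolerance = 1e-12)
  expect_error(steiger_overlapping(0.9, -0.9, 0.9, 36), "embeddable")
})

test_that("Steiger's Z is standard normal under the null", {
  set.seed(99)
  n <- 36; reps <- 5000
  rho <- 0.4  # equal true correlations r_jk = r_jh
  R <- matrix(c(1, rho, rho, rho, 1, 0.3, rho, 0.3, 1), 3, 3)
  L <- chol(R)
  z <- replicate(reps, {
    X <- matrix(rnorm(3 * n), n) %*% L
    r <- cor(X)
    steiger_overlapping(r[1, 2], r[1, 3], r[2, 3], n)$z
  })
  expect_lt(abs(mean(abs(z) > qnorm(0.975)) - 0.05), 0.012)
  expect_gt(suppressWarnings(ks.test(z, "pnorm"))$p.value, 0.01)
})

test_that("the sequential stopping rule fires at the first decisive checkpoint", {
  # decisive immediately
  tr <- sequential_stopping(list(c(5, 0.1)))
  expect_equal(tr$n_final, 24)
  # inconclusive at 24, decisive at 28
  tr2 <- sequential_stopping(list(c(5, 1.2), c(5, 0.2)))
  expect_equal(tr2$n_final, 28)
  expect_equal(tr2$checkpoints$decision, c("continue", "stop"))
  # never decisive
  tr3 <- sequential_stopping(list(c(1), c(2), c(0.5)))
  expect_true(is.na(tr3$n_final))
  expect_true(all(tr3$checkpoints$decision == "continue"))
  expect_error(sequential_stopping(list(1), upper = 0.3, lower = 3), "lower")
})

test_that("hierarchical correlation draws are valid correlation matrices and a duplicated task correlates with itself", {
  set.seed(55)
  # 12 subjects, two real tasks plus a duplicate of the first
  obs_eff <- exp(rnorm(12, 0, 0.4))
  counts <- lapply(seq_len(12), function(i) {
    t2 <- c(-1.5, -1, -0.5, 0.5, 1, 1.5)
    probs <- model_predicted_probs(1.2, 0, 1.2 * obs_eff[i], t2, 4)
    a <- sample_counts_from_probs(probs, 150)
    probs_b <- model_predicted_probs(1.1, 0, 1.1 * exp(rnorm(1, 0, 0.4)), t2, 4)
    b <- sample_counts_from_probs(probs_b, 150)
    list(t1 = a, t2 = b, t1dup = a)
  })
  h <- fit_hierarchical_efficiency(
    counts, mcmc_settings(n_chains = 2, n_adapt = 300, n_burnin = 300,
                          n_iter = 400, seed = 9))
  # every draw is a valid correlation matrix
  ok <- apply(h$rho_draws, 1, function(m) {
    M <- matrix(m, 3, 3)
    all(abs(diag(M) - 1) < 1e-9) && isTRUE(all.equal(M, t(M))) &&
      min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > -1e-8
  })
  expect_true(all(ok))
  # identical data for t1 and t1dup: their correlation posterior is pulled
  # toward 1, limited only by the weak per-subject likelihood
  dup <- h$pairs[h$pairs$task1 == "t1" & h$pairs$task2 == "t1dup", ]
  expect_gt(dup$rho_mean, 0.7)
  expect_true(dup$significant)
  expect_equal(which.max(h$pairs$rho_mean),
               which(h$pairs$task1 == "t1" & h$pairs$task2 == "t1dup"))
})

test_that("hierarchical fit validates its inputs", {
  cts <- collate_type2_counts(
    data.frame(test_interval = rep(1:2, 30),
               response_interval = sample(1:2, 60, TRUE),
               confidence = sample(1:4, 60, TRUE)))
  expect_error(fit_hierarchical_efficiency(list(list(a = cts))), "2 subjects")
  expect_error(fit_hierarchical_efficiency(
    list(list(a = cts, b = cts), list(a = cts))), "same tasks")
})
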