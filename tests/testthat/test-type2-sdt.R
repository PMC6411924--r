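make_trials <- function(test, resp, conf) {
  data.frame(test_interval = test, response_interval = resp,
             confidence = conf)
}

test_that("confidence counts tabulate by stimulus, response and confidence", {
  tr <- make_trials(c(1, 1, 2, 2, 1), c(1, 2, 2, 1, 1), c(4, 1, 3, 2, 4))
  cts <- collate_type2_counts(tr, K = 4)
  expect_equal(sum(cts), 5)
  expect_equal(cts["S1", "R1", "4"], 2)
  expect_equal(cts["S1", "R2", "1"], 1)
  expect_equal(cts["S2", "R2", "3"], 1)
  # per-class totals equal the analysed trials of that class
  expect_equal(apply(cts, 1, sum), c(S1 = 3, S2 = 2))
  # degenerate log: a single nonzero cell
  one <- collate_type2_counts(make_trials(rep(1, 6), rep(1, 6), rep(4, 6)))
  expect_equal(sum(one > 0), 1)
  expect_equal(one["S1", "R1", "4"], 6)
})

test_that("uniform padding adds 1/(2K) to every cell", {
  tr <- make_trials(c(1, 2), c(1, 2), c(2, 3))
  raw <- collate_type2_counts(tr, K = 4, padding = "none")
  pad <- collate_type2_counts(tr, K = 4, padding = "uniform")
  expect_equal(unclass(pad) - unclass(raw), array(0.125, c(2, 2, 4)),
               ignore_attr = TRUE)
})

test_that("malformed trial input is rejected with a data error", {
  expect_error(collate_type2_counts(make_trials(1, 1, 5), K = 4), "confidence")
  expect_error(collate_type2_counts(make_trials(numeric(0), numeric(0),
                                                numeric(0))), "trials")
  expect_error(collate_type2_counts(data.frame(confidence = 1)), "missing")
})

test_that("type-1 estimates follow the equal-variance Gaussian formulas", {
  expect_equal(type1_sdt(0.5, 0.5)$d_prime, 0)
  t1 <- type1_sdt(0.8, 0.2)
  expect_equal(t1$d_prime, 2 * qnorm(0.8), tolerance = 1e-9)  # approx 1.683
  expect_equal(t1$criterion_c, 0)
  expect_error(type1_sdt(1, 0.2), "padding")
})

test_that("relabelling stimulus classes and responses negates c, keeps d'", {
  set.seed(5)
  tr <- simulate_observer_trials(observer_spec(1, type1_criterion = 0.3), 800)
  cts <- collate_type2_counts(tr)
  flipped <- tr
  flipped$test_interval <- 3L - tr$test_interval
  flipped$response_interval <- 3L - tr$response_interval
  cts_f <- collate_type2_counts(flipped)
  a <- estimate_type1(cts); b <- estimate_type1(cts_f)
  expect_equal(a$d_prime, b$d_prime, tolerance = 1e-9)
  expect_equal(a$criterion_c, -b$criterion_c, tolerance = 1e-9)
  # meta-d' is invariant under the joint relabelling too
  fa <- fit_meta_d_mle(cts); fb <- fit_meta_d_mle(cts_f)
  expect_equal(fa$meta_d, fb$meta_d, tolerance = 1e-4)
})

test_that("model probabilities normalise and degenerate limits behave", {
  t2 <- c(-1.5, -1, -0.5, 0.5, 1, 1.5)
  for (pars in list(c(1.2, 0, 1.2), c(0.8, 0.25, 0.4), c(2, -0.3, 1.4))) {
    mc <- metaconf:::meta_criterion(pars[3], pars[1], pars[2])
    probs <- model_predicted_probs(pars[1], pars[2], pars[3], t2 + mc, K = 4)
    expect_equal(apply(probs, 1, sum), c(S1 = 1, S2 = 1), tolerance = 1e-10)
  }
  # meta_d = 0: confidence carries no information about the stimulus, so the
  # confidence distribution is identical across stimulus classes
  p0 <- model_predicted_probs(1.2, 0, 0, t2, K = 4)
  cond_s1 <- p0["S1", "R1", ] / sum(p0["S1", "R1", ])
  cond_s2 <- p0["S2", "R1", ] / sum(p0["S2", "R1", ])
  expect_equal(cond_s1, cond_s2, tolerance = 1e-12)
  expect_error(model_predicted_probs(1.2, 0, 1.2, c(1, 0.5, -0.5, -1, 1.5, 2)),
               "increasing")
})

test_that("MLE recovers the generating parameters from expected counts", {
  t2 <- c(-1.6, -1.0, -0.45, 0.5, 1.05, 1.6)
  for (gen in list(c(d = 1.2, eff = 1), c(d = 1.2, eff = 0.6),
                   c(d = 0.9, eff = 1.3))) {
    meta_d <- gen[["d"]] * gen[["eff"]]
    probs <- model_predicted_probs(gen[["d"]], 0, meta_d, t2, 4)
    counts <- as_type2_counts(probs * 20000)
    fit <- fit_meta_d_mle(counts)
    expect_equal(fit$efficiency_ratio, gen[["eff"]], tolerance = 0.02)
    expect_true(fit$converged)
  }
})

test_that("confidence shuffled independently of accuracy gives meta-d' near 0", {
  set.seed(11)
  tr <- simulate_observer_trials(observer_spec(1, efficiency = 1), 4000)
  tr$confidence <- sample(tr$confidence)   # break the confidence-accuracy link
  fit <- fit_meta_d_mle(collate_type2_counts(tr))
  expect_lt(abs(fit$meta_d), 0.15)
})

test_that("efficiency identities hold exactly", {
  set.seed(2)
  tr <- simulate_observer_trials(observer_spec(1, efficiency = 0.8), 600)
  fit <- fit_meta_d_mle(collate_type2_counts(tr))
  expect_equal(fit$efficiency_ratio * fit$d_prime, fit$meta_d,
               tolerance = 1e-12)
  expect_equal(fit$efficiency_diff,
               fit$efficiency_ratio * fit$d_prime - fit$d_prime,
               tolerance = 1e-12)
})

test_that("fitted meta-d' decreases with generative meta-level degradation", {
  set.seed(31)
  effs <- c(1.2, 0.9, 0.6, 0.3)
  fitted <- vapply(effs, function(e) {
    tr <- simulate_observer_trials(observer_spec(1, efficiency = e), 3000)
    fit_meta_d_mle(collate_type2_counts(tr))$meta_d
  }, numeric(1))
  expect_true(all(diff(fitted) < 0))
})

test_that("MLE optimum dominates an exhaustive grid search (K = 2)", {
  set.seed(19)
  # small-count instances, compared against an iteratively refined
  # brute-force grid over (meta_d, criterion distances)
  for (rep in 1:3) {
    t2 <- c(-0.4 - runif(1), 0.4 + runif(1))
    probs <- model_predicted_probs(1 + runif(1), 0.2 * rnorm(1),
                                   runif(1, 0.4, 1.4), t2, K = 2)
    counts <- sample_counts_from_probs(probs, 60)
    fit <- fit_meta_d_mle(counts)
    padded <- unclass(counts) + 1 / 4
    grid <- grid_fit_meta_d_k2(padded, fit$criterion_c / fit$d_prime)
    ll_grid_at_fit <- grid$ll
    # conditional log-likelihood of the optimiser's solution, via the oracle
    a <- fit$criterion_c / fit$d_prime * fit$meta_d - fit$t2_criteria[1]
    b <- fit$t2_criteria[2] - fit$criterion_c / fit$d_prime * fit$meta_d
    ll_fit <- grid_loglik_k2(padded, fit$meta_d, a, b,
                             fit$criterion_c / fit$d_prime)
    expect_gte(ll_fit, grid$ll - 1e-4)
    expect_equal(fit$meta_d, grid$meta_d, tolerance = 2e-3)
  }
})

test_that("Bayesian fit agrees with MLE and flags flat confidence", {
  set.seed(23)
  t2 <- c(-1.6, -1.05, -0.4, 0.6, 1.15, 1.7)
  probs <- model_predicted_probs(1.1, 0.1, 0.9, t2, 4)
  counts <- sample_counts_from_probs(probs, 400)
  mle <- fit_meta_d_mle(counts)
  bay <- fit_meta_d_bayes(counts, mcmc_settings(seed = 4))
  expect_true(bay$converged)
  post_sd <- bay$posterior_summary$meta_d[["sd"]]
  expect_lt(abs(bay$meta_d - mle$meta_d), post_sd)
  # flat confidence: no type-2 information, so the efficiency posterior
  # stays close to its (wide) log-normal prior instead of updating
  flat <- array(0, c(2, 2, 4)); flat[, , 1] <- 50
  flat_fit <- fit_meta_d_bayes(as_type2_counts(flat), mcmc_settings(seed = 5))
  ratio_ci <- flat_fit$posterior_summary$efficiency_ratio
  expect_lt(ratio_ci[["2.5%"]], 0.35)   # prior 2.5% quantile is exp(-1.96)
  expect_gt(ratio_ci[["97.5%"]], 3)     # prior 97.5% quantile is exp(+1.96)
})

test_that("Bayesian fit recovers parameters from large samples", {
  set.seed(29)
  t2 <- c(-1.6, -1.05, -0.4, 0.6, 1.15, 1.7)
  probs <- model_predicted_probs(1.2, 0, 1.02, t2, 4)
  counts <- sample_counts_from_probs(probs, 6000)
  fit <- fit_meta_d_bayes(counts, mcmc_settings(seed = 6))
  expect_equal(fit$meta_d, 1.02, tolerance = 0.05)
  expect_true(fit$converged)
})

test_that("subject measures summarise a session correctly", {
  toy <- data.frame(test_interval = rep(1:2, 10), response_interval = rep(1:2, 10),
                    confidence = 4, correct = TRUE)
  m <- subject_measures(toy)
  expect_equal(m$pct_correct, 1)
  expect_equal(m$mean_confidence, 4)
  set.seed(13)
  obs <- observer_spec(0.5, efficiency = 1)
  sess <- simulate_session(obs, staircase_config(45, 47, 0.5, 50))
  analysed <- sess[!sess$is_practice, ]
  m2 <- subject_measures(analysed)
  expect_gt(m2$pct_correct, 0.6)
  expect_lt(m2$pct_correct, 0.8)
  expect_equal(m2$efficiency_ratio, 1, tolerance = 0.45)  # n = 160 sampling error
})
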