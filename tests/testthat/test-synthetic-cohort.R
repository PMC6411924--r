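test_that("trial outcomes are at chance when the stimuli are identical", {
  set.seed(3)
  obs <- observer_spec(1)
  tr <- simulate_observer_trials(obs, 4000, delta = 0)
  expect_equal(mean(tr$correct), 0.5, tolerance = 0.025)
})

test_that("generated trials recover the generating d' and efficiency", {
  set.seed(17)
  obs <- observer_spec(1, efficiency = 1)
  tr <- simulate_observer_trials(obs, 8000, delta = 1.2)
  t1 <- estimate_type1(collate_type2_counts(tr))
  expect_equal(t1$d_prime, 1.2, tolerance = 0.07)
  fit <- fit_meta_d_mle(collate_type2_counts(tr))
  expect_equal(fit$efficiency_ratio, 1, tolerance = 0.07)
})

test_that("generated confidence counts match the model's predicted table", {
  set.seed(41)
  # chi-square goodness of fit of simulated counts against the generating
  # model's joint probabilities
  obs <- observer_spec(1, type1_criterion = 0.15, efficiency = 0.8)
  n <- 20000
  tr <- simulate_observer_trials(obs, n, delta = 1.1)
  cts <- collate_type2_counts(tr)
  mc <- metaconf:::meta_criterion(0.8 * 1.1, 1.1, 0.15)
  t2 <- c(mc - rev(obs$confidence_thresholds), mc + obs$confidence_thresholds)
  probs <- model_predicted_probs(1.1, 0.15, 0.8 * 1.1, t2, 4)
  n_s1 <- sum(cts["S1", , ]); n_s2 <- sum(cts["S2", , ])
  expected <- c(probs["S1", , ] * n_s1, probs["S2", , ] * n_s2)
  observed <- c(unclass(cts)["S1", , ], unclass(cts)["S2", , ])
  keep <- expected > 5
  chisq <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chisq, df = sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("sessions have the study's structure and obey the staircase caps", {
  set.seed(23)
  obs <- observer_spec(0.28, efficiency = 1)
  sess <- simulate_session(obs, staircase_config(38, 40, 0.5, 43),
                           task = "warmth")
  expect_equal(nrow(sess), 180)
  expect_equal(sum(sess$is_practice), 20)
  expect_equal(sum(!sess$is_practice), 160)
  expect_true(all(sess$test_intensity <= 43))
  expect_true(all(sess$test_intensity >= 38.5))
  expect_true(all(sess$correct == (sess$response_interval == sess$test_interval)))
})

test_that("a long session converges to the staircase equilibrium accuracy", {
  set.seed(29)
  obs <- observer_spec(0.5, efficiency = 1)
  sess <- simulate_session(obs, staircase_config(45, 47, 0.5, 50),
                           n_trials = 4000, n_practice = 500, task = "pain")
  expect_equal(mean(sess$correct[!sess$is_practice]), asymptotic_accuracy(2),
               tolerance = 0.02)
})

test_that("cohorts are byte-identical under the same seed", {
  spec <- cohort_spec(n_subjects = 3, seed = 77)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ratings, b$ratings)
  expect_identical(a$subjects, b$subjects)
  c_ <- simulate_cohort(cohort_spec(n_subjects = 3, seed = 78))
  expect_false(identical(a$trials, c_$trials))
})

test_that("invalid correlation matrices are rejected", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(cohort_spec(efficiency_correlations = bad), "correlation")
})

test_that("uncorrelated generating efficiency yields near-zero fitted cross-task correlations", {
  spec <- cohort_spec(n_subjects = 120, efficiency_correlations = diag(3),
                      bias_correlations = diag(3), seed = 5)
  ds <- simulate_cohort(spec)
  an <- ds$trials[!ds$trials$is_practice, ]
  eff <- sapply(sort(unique(an$task)), function(tk)
    sapply(unique(an$subject), function(s) {
      fit_meta_d_mle(collate_type2_counts(
        an[an$subject == s & an$task == tk, ]))$efficiency_ratio
    }))
  r <- cor(eff)
  expect_true(all(abs(r[upper.tri(r)]) < 0.2))
})

test_that("correlated confidence bias shows up in mean confidence", {
  R <- matrix(c(1, 0.2, 0.2, 0.2, 1, 0.8, 0.2, 0.8, 1), 3, 3)
  ds <- simulate_cohort(cohort_spec(n_subjects = 150,
                                    bias_correlations = R, seed = 6))
  an <- ds$trials[!ds$trials$is_practice, ]
  mc <- sapply(sort(unique(an$task)), function(tk)
    sapply(unique(an$subject), function(s)
      mean(an$confidence[an$subject == s & an$task == tk])))
  # tasks ordered pain, vision, warmth; generating bias correlation 0.8 is
  # between tasks 2 and 3 of the spec's ordering (warmth-pain)
  r_wp <- cor(mc[, "warmth"], mc[, "pain"])
  expect_equal(r_wp, 0.8, tolerance = 0.15)
})
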