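#' Specify a simulated observer
#'
#' A generative observer for one subject-task. The type-1 decision follows an
#' equal-variance Gaussian SDT model whose sensitivity grows linearly with the
#' physical test-minus-reference difference: d' = `psychometric_slope` x
#' delta. Confidence is generated by a meta-level observer with sensitivity
#' meta-d' = `efficiency` x d' whose criterion sits at the same relative
#' position as the type-1 criterion (the exact generative law of the type-2
#' model that [fit_meta_d_mle()] and [fit_meta_d_bayes()] estimate), so the
#' fitted efficiency converges to the generating `efficiency` by
#' construction, including values above 1 where confidence carries more
#' stimulus information than the first-order decision.
#'
#' @param psychometric_slope d' per unit intensity difference (> 0).
#' @param type1_criterion Type-1 criterion (z-units).
#' @param efficiency Generative meta-d'/d' target (> 0).
#' @param confidence_thresholds Increasing vector of K-1 positive distances
#'   of the type-2 criteria from the meta-level criterion (z-units).
#' @param confidence_bias Scalar subtracted from all cutpoint distances;
#'   positive values raise mean confidence. Shifted cutpoints are floored at
#'   a small positive spacing, so an extreme bias saturates the scale rather
#'   than inverting it.
#' @return An `observer_spec`.
#' @export
observer_spec <- function(psychometric_slope, type1_criterion = 0,
                          efficiency = 1,
                          confidence_thresholds = c(0.25, 0.7, 1.3),
                          confidence_bias = 0) {
  stopifnot(psychometric_slope > 0, efficiency > 0,
            all(diff(confidence_thresholds) > 0))
  structure(list(psychometric_slope = psychometric_slope,
                 type1_criterion = type1_criterion,
                 efficiency = efficiency,
                 confidence_thresholds = confidence_thresholds,
                 confidence_bias = confidence_bias),
            class = "observer_spec")
}

#' Simulate one 2IFC trial
#'
#' @param observer An [observer_spec()].
#' @param delta Non-negative test-minus-reference intensity difference.
#' @param test_interval Interval (1 or 2) containing the test stimulus.
#' @return List with `response_interval` (1 or 2) and `confidence`
#'   (1..K where K = length(confidence_thresholds) + 1).
#' @export
sample_trial_outcome <- function(observer, delta, test_interval) {
  stopifnot(delta >= 0, test_interval %in% 1:2)
  K <- length(observer$confidence_thresholds) + 1L
  d <- observer$psychometric_slope * delta
  cc <- observer$type1_criterion
  meta_d <- observer$efficiency * d
  mc <- meta_criterion(meta_d, d, cc)
  tau <- observer$confidence_thresholds - observer$confidence_bias
  tau[1] <- max(tau[1], 0.05)
  for (j in seq_along(tau)[-1]) tau[j] <- max(tau[j], tau[j - 1] + 0.05)
  t2 <- c(mc - rev(tau), mc + tau)
  parts <- type2_cond_probs(d, cc, meta_d, t2, K)
  s <- test_interval                       # S1 = test in interval 1
  response <- sample(1:2, 1, prob = parts$p_response[s, ])
  conf <- sample.int(K, 1, prob = parts$cond[s, response, ])
  list(response_interval = as.integer(response), confidence = conf)
}

#' Simulate one staircase-controlled session
#'
#' Runs a full task session: on every trial the test stimulus takes the
#' staircase's current intensity, the observer responds, correctness is
#' defined by the physical intensity ordering (the test is always the more
#' intense stimulus), and the staircase is updated with the outcome. The
#' first `n_practice` trials are flagged as practice.
#'
#' @param observer An [observer_spec()].
#' @param staircase A [staircase_config()].
#' @param n_trials Total trials (180 in the reference design).
#' @param n_practice Practice trials excluded from analysis (20).
#' @param subject,task,session Identifiers copied into the records.
#' @return A data frame of trial records (see [read_trials_csv()] for the
#'   schema).
#' @export
simulate_session <- function(observer, staircase, n_trials = 180L,
                             n_practice = 20L, subject = "s01",
                             task = "vision", session = 1L) {
  state <- init_staircase(staircase, record_history = FALSE)
  intensity <- numeric(n_trials)
  test_interval <- integer(n_trials)
  response_interval <- integer(n_trials)
  confidence <- integer(n_trials)
  correct <- logical(n_trials)
  for (tr in seq_len(n_trials)) {
    intensity[tr] <- staircase_intensity(state)
    delta <- intensity[tr] - staircase$reference_intensity
    test_interval[tr] <- sample(1:2, 1)
    out <- sample_trial_outcome(observer, delta, test_interval[tr])
    response_interval[tr] <- out$response_interval
    confidence[tr] <- out$confidence
    correct[tr] <- out$response_interval == test_interval[tr]
    state <- update_staircase(state, correct[tr])
  }
  data.frame(
    subject = subject, task = task, session = as.integer(session),
    block = as.integer(ceiling(seq_len(n_trials) / 20)),
    trial = seq_len(n_trials),
    is_practice = seq_len(n_trials) <= n_practice,
    reference_intensity = staircase$reference_intensity,
    test_intensity = intensity,
    test_interval = test_interval, response_interval = response_interval,
    correct = correct, confidence = confidence)
}

default_task_specs <- function() {
  list(
    vision = list(staircase = staircase_config(50, 70, 3, 100),
                  slope = 0.09, session = 1L),
    warmth = list(staircase = staircase_config(38, 40, 0.5, 43),
                  slope = 0.28, session = 1L),
    pain = list(staircase = staircase_config(45, 47, 0.5, 50),
                slope = 0.50, session = 2L))
}

#' Specify a synthetic cohort
#'
#' Defaults emulate the reference study: 36 subjects x 3 tasks (visual
#' contrast, innocuous warmth, noxious heat) x 180 trials with a 20-trial
#' practice block, staircase-controlled difficulty near 70.7\% correct and
#' subject-level d' near 1.0-1.3. Between-subject log-efficiency and
#' confidence-bias vectors are drawn from multivariate normals with the given
#' cross-task correlation matrices; by default efficiency is correlated for
#' vision-warmth (0.7) but not vision-pain (0), while confidence bias is
#' positively correlated across all tasks. The warmth psychometric slope is
#' set low enough that some subjects reach the 43.0 C cap, reproducing the
#' slight warmth accuracy deficit of the reference design.
#'
#' @param n_subjects Number of subjects.
#' @param tasks Named list of per-task settings (staircase config, slope,
#'   session); see `metaconf:::default_task_specs()`.
#' @param n_trials,n_practice Trials per session and practice-block size.
#' @param log_efficiency_mean,log_efficiency_sd Per-task mean and SD of
#'   subject log(meta-d'/d').
#' @param efficiency_correlations,bias_correlations 3 x 3 correlation
#'   matrices across tasks (must be valid correlation matrices).
#' @param bias_sd SD of the confidence-bias shift.
#' @param slope_log_sd Between-subject SD of log psychometric slope.
#' @param criterion_sd Between-subject SD of the type-1 criterion.
#' @param rating_warm_mean,rating_gap_mean,rating_between_sd,rating_gap_sd,rating_within_sd
#'   Manipulation-check rating model: subject mean painfulness of the warmest
#'   innocuous stimulus, mean noxious-minus-warm gap, their between-subject
#'   SDs, and the within-subject trial SD (4-point scale).
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 36L, tasks = default_task_specs(),
                        n_trials = 180L, n_practice = 20L,
                        log_efficiency_mean = log(c(vision = 0.90,
                                                    warmth = 1.00,
                                                    pain = 0.88)),
                        log_efficiency_sd = c(0.35, 0.35, 0.35),
                        efficiency_correlations =
                          matrix(c(1, 0.7, 0,
                                   0.7, 1, 0.35,
                                   0, 0.35, 1), 3, 3),
                        bias_correlations =
                          matrix(c(1, 0.6, 0.6,
                                   0.6, 1, 0.8,
                                   0.6, 0.8, 1), 3, 3),
                        bias_sd = 0.3, slope_log_sd = 0.25,
                        criterion_sd = 0.1,
                        rating_warm_mean = 1.88, rating_gap_mean = 0.59,
                        rating_between_sd = 0.45, rating_gap_sd = 0.5,
                        rating_within_sd = 0.8,
                        seed = 1L) {
  check_corr <- function(M, name) {
    if (!isTRUE(all.equal(M, t(M))) || any(abs(diag(M) - 1) > 1e-12) ||
        any(eigen(M, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop(name, " is not a valid correlation matrix", call. = FALSE)
  }
  check_corr(efficiency_correlations, "efficiency_correlations")
  check_corr(bias_correlations, "bias_correlations")
  stopifnot(length(tasks) == nrow(efficiency_correlations))
  structure(as.list(environment())[c(
    "n_subjects", "tasks", "n_trials", "n_practice", "log_efficiency_mean",
    "log_efficiency_sd", "efficiency_correlations", "bias_correlations",
    "bias_sd", "slope_log_sd", "criterion_sd", "rating_warm_mean",
    "rating_gap_mean", "rating_between_sd", "rating_gap_sd",
    "rating_within_sd", "seed")], class = "cohort_spec")
}

# correlated standard-normal draws via the Cholesky factor; a tiny ridge
# keeps singular (e.g. duplicated-task) correlation matrices usable
rmvn_corr <- function(n, R) {
  L <- chol(R + diag(1e-10, nrow(R)))
  matrix(stats::rnorm(n * nrow(R)), n) %*% L
}

session_seed <- function(seed, subj, task_idx) {
  as.integer((as.numeric(seed) * 100003 + subj * 1009 + task_idx * 101) %%
               2147483629)
}

#' Simulate a full study dataset
#'
#' Draws per-subject parameter vectors (log-efficiency and confidence bias
#' from the specified correlated multivariate normals; psychometric slope and
#' criterion independently), then simulates one staircase-controlled session
#' per subject-task plus the 20-trial painfulness-rating manipulation check.
#' Fully reproducible from `spec$seed`: subject-level draws use one stream
#' seeded by `seed`, and each session re-seeds a stream with a documented
#' (seed, subject, task) hash.
#'
#' @param spec A [cohort_spec()].
#' @return A `study_dataset`: list with `trials` (trial records), `ratings`
#'   (manipulation-check records), `subjects` (the generating parameters) and
#'   the spec.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  tasks <- names(spec$tasks)
  Tn <- length(tasks)
  log_eff <- sweep(rmvn_corr(n, spec$efficiency_correlations) %*%
                     diag(spec$log_efficiency_sd), 2,
                   spec$log_efficiency_mean, "+")
  bias <- rmvn_corr(n, spec$bias_correlations) * spec$bias_sd
  slopes <- sweep(exp(matrix(stats::rnorm(n * Tn, 0, spec$slope_log_sd), n, Tn)),
                  2, vapply(spec$tasks, function(tk) tk$slope, numeric(1)), "*")
  crits <- matrix(stats::rnorm(n * Tn, 0, spec$criterion_sd), n, Tn)
  warm_mean <- stats::rnorm(n, spec$rating_warm_mean, spec$rating_between_sd)
  gap <- stats::rnorm(n, spec$rating_gap_mean, spec$rating_gap_sd)
  subjects <- data.frame(
    subject = sprintf("s%02d", seq_len(n)),
    do.call(cbind, stats::setNames(lapply(seq_len(Tn), function(t)
      data.frame(eff = exp(log_eff[, t]), bias = bias[, t],
                 slope = slopes[, t], criterion = crits[, t])), tasks)),
    rating_warm = warm_mean, rating_noxious = warm_mean + gap)
  trials <- vector("list", n * Tn)
  ratings <- vector("list", n)
  for (i in seq_len(n)) {
    for (t in seq_len(Tn)) {
      obs <- observer_spec(psychometric_slope = slopes[i, t],
                           type1_criterion = crits[i, t],
                           efficiency = exp(log_eff[i, t]),
                           confidence_bias = bias[i, t])
      set.seed(session_seed(spec$seed, i, t))
      trials[[(i - 1) * Tn + t]] <- simulate_session(
        obs, spec$tasks[[t]]$staircase, n_trials = spec$n_trials,
        n_practice = spec$n_practice, subject = subjects$subject[i],
        task = tasks[t], session = spec$tasks[[t]]$session)
    }
    set.seed(session_seed(spec$seed, i, Tn + 1L))
    discretize <- function(mu, k = 10L)
      pmin(pmax(round(stats::rnorm(k, mu, spec$rating_within_sd)), 1L), 4L)
    ratings[[i]] <- data.frame(
      subject = subjects$subject[i],
      stimulus_kind = rep(c("max_warm", "min_noxious"), each = 10L),
      temperature = rep(c(42.7, 45.0), each = 10L),
      rating = c(discretize(warm_mean[i]),
                 discretize(warm_mean[i] + gap[i])))
  }
  structure(list(trials = do.call(rbind, trials),
                 ratings = do.call(rbind, ratings),
                 subjects = subjects, spec = spec),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("Synthetic study dataset: %d subjects x %d tasks x %d trials (%d practice)\n",
              x$spec$n_subjects, length(x$spec$tasks), x$spec$n_trials,
              x$spec$n_practice))
  cat(sprintf("  %d trial records, %d rating records, seed %d\n",
              nrow(x$trials), nrow(x$ratings), x$spec$seed))
  invisible(x)
}
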