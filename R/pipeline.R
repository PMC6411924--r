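trial_schema <- c("subject", "task", "session", "block", "trial",
                  "is_practice", "reference_intensity", "test_intensity",
                  "test_interval", "response_interval", "correct",
                  "confidence")

#' Read / write trial logs
#'
#' The trial CSV holds one row per 2IFC trial with columns `subject`, `task`,
#' `session`, `block`, `trial`, `is_practice`, `reference_intensity`,
#' `test_intensity`, `test_interval` (1 or 2), `response_interval` (1 or 2),
#' `correct` and `confidence` (1..K). Comma-separated, dot decimal, UTF-8,
#' header required. Malformed rows are reported with their line numbers.
#'
#' @param path File path.
#' @param K Number of confidence levels used for validation.
#' @return `read_trials_csv` returns the validated trial data frame.
#' @export
read_trials_csv <- function(path, K = 4L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_schema, names(df))
  if (length(missing_cols))
    stop("trial CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$is_practice <- as.logical(df$is_practice)
  df$correct <- as.logical(df$correct)
  bad <- which(!(df$test_interval %in% 1:2) |
                 !(df$response_interval %in% 1:2) |
                 !(df$confidence %in% seq_len(K)) |
                 is.na(df$is_practice) | is.na(df$correct))
  if (length(bad))
    stop("invalid trial rows at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " (line 1 is the header): test/response interval must be 1 or 2, ",
         "confidence must lie in 1..", K, call. = FALSE)
  df[trial_schema]
}

#' @rdname read_trials_csv
#' @param trials Trial data frame (or a `study_dataset`, whose `trials`
#'   element is written).
#' @export
write_trials_csv <- function(trials, path) {
  if (inherits(trials, "study_dataset")) trials <- trials$trials
  utils::write.csv(trials[trial_schema], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

rating_schema <- c("subject", "stimulus_kind", "temperature", "rating")

#' Read / write manipulation-check rating logs
#'
#' One row per painfulness rating with columns `subject`, `stimulus_kind`
#' (`max_warm` or `min_noxious`), `temperature` (degrees C) and `rating`
#' (1..4).
#'
#' @param path File path.
#' @return `read_ratings_csv` returns the validated rating data frame.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(rating_schema, names(df))
  if (length(missing_cols))
    stop("ratings CSV is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!(df$rating %in% 1:4) |
                 !(df$stimulus_kind %in% c("max_warm", "min_noxious")))
  if (length(bad))
    stop("invalid rating rows at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), call. = FALSE)
  df[rating_schema]
}

#' @rdname read_ratings_csv
#' @param ratings Rating data frame (or a `study_dataset`).
#' @export
write_ratings_csv <- function(ratings, path) {
  if (inherits(ratings, "study_dataset")) ratings <- ratings$ratings
  utils::write.csv(ratings[rating_schema], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' @param K Number of confidence levels.
#' @param fit_method Per-subject meta-d' estimator: `"mle"` (fast, uniformly
#'   padded counts) or `"bayes"` (single-subject Bayesian fit on raw counts).
#' @param chance_exclusion Apply the chance-level rule: a subject whose
#'   analysed accuracy in any task is not above 0.5 by a one-sided binomial
#'   test at `chance_alpha` is excluded entirely.
#' @param chance_alpha Alpha for the chance-level binomial test.
#' @param manipulation_exclusion Optional sensitivity rule: exclude subjects
#'   whose mean painfulness rating of the lowest noxious stimulus does not
#'   exceed that of the warmest innocuous stimulus.
#' @param hierarchical Fit the hierarchical cross-task efficiency model in
#'   [run_full_analysis()].
#' @param mcmc [mcmc_settings()] for the Bayesian fits.
#' @param seed Seed for any stochastic analysis step.
#' @return An `analysis_config`.
#' @export
analysis_config <- function(K = 4L, fit_method = c("mle", "bayes"),
                            chance_exclusion = TRUE, chance_alpha = 0.05,
                            manipulation_exclusion = FALSE,
                            hierarchical = TRUE, mcmc = mcmc_settings(),
                            seed = 1L) {
  structure(list(K = as.integer(K), fit_method = match.arg(fit_method),
                 chance_exclusion = chance_exclusion,
                 chance_alpha = chance_alpha,
                 manipulation_exclusion = manipulation_exclusion,
                 hierarchical = hierarchical, mcmc = mcmc,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Apply subject-level exclusion rules
#'
#' Chance-level rule: a subject is removed entirely if their analysed
#' accuracy in any task is not above 0.5 by a one-sided exact binomial test.
#' Manipulation-check rule (optional): a subject is removed if their mean
#' painfulness rating of the lowest noxious stimulus does not exceed that of
#' the warmest innocuous stimulus. The audit lists every removed subject and
#' the triggering rule.
#'
#' @param trials Trial data frame (or `study_dataset`).
#' @param ratings Rating data frame; required for the manipulation rule.
#' @param config An [analysis_config()].
#' @return List with filtered `trials` and `ratings`, and the `audit` data
#'   frame (`subject`, `rule`, `detail`).
#' @export
apply_exclusions <- function(trials, ratings = NULL,
                             config = analysis_config()) {
  if (inherits(trials, "study_dataset")) {
    if (is.null(ratings)) ratings <- trials$ratings
    trials <- trials$trials
  }
  analysed <- trials[!trials$is_practice, ]
  audit <- data.frame(subject = character(0), rule = character(0),
                      detail = character(0))
  excluded <- character(0)
  if (isTRUE(config$chance_exclusion)) {
    for (subj in unique(analysed$subject)) {
      for (task in unique(analysed$task[analysed$subject == subj])) {
        sub <- analysed[analysed$subject == subj & analysed$task == task, ]
        p <- stats::binom.test(sum(sub$correct), nrow(sub), 0.5,
                               alternative = "greater")$p.value
        if (p >= config$chance_alpha) {
          excluded <- union(excluded, subj)
          audit <- rbind(audit, data.frame(
            subject = subj, rule = "chance_level",
            detail = sprintf("%s accuracy %.1f%% (p = %.3f)", task,
                             100 * mean(sub$correct), p)))
          break
        }
      }
    }
  }
  if (isTRUE(config$manipulation_exclusion)) {
    if (is.null(ratings))
      stop("manipulation-check exclusion requires ratings", call. = FALSE)
    for (subj in setdiff(unique(analysed$subject), excluded)) {
      rs <- ratings[ratings$subject == subj, ]
      gap <- mean(rs$rating[rs$stimulus_kind == "min_noxious"]) -
        mean(rs$rating[rs$stimulus_kind == "max_warm"])
      if (!is.na(gap) && gap <= 0) {
        excluded <- union(excluded, subj)
        audit <- rbind(audit, data.frame(
          subject = subj, rule = "manipulation_check",
          detail = sprintf("noxious - warm rating gap = %.2f", gap)))
      }
    }
  }
  list(trials = trials[!trials$subject %in% excluded, ],
       ratings = if (!is.null(ratings))
         ratings[!ratings$subject %in% excluded, ],
       audit = audit)
}

#' Manipulation check: painfulness of noxious vs innocuous heat
#'
#' Summarises the 20-trial rating task (10 ratings of the warmest innocuous
#' stimulus, 10 of the lowest noxious stimulus per subject) and tests the
#' per-subject mean difference with a paired JZS Bayes factor.
#'
#' @param ratings Rating data frame (see [read_ratings_csv()]).
#' @return List with the per-kind descriptives (`means`: mean and 95\%
#'   t-interval), the per-subject means, and `bf` (a `bf_result`).
#' @export
manipulation_check <- function(ratings) {
  by_subj <- stats::aggregate(rating ~ subject + stimulus_kind, ratings, mean)
  wide <- stats::reshape(by_subj, idvar = "subject",
                         timevar = "stimulus_kind", direction = "wide")
  if (anyNA(wide))
    stop("every subject needs ratings of both stimulus kinds", call. = FALSE)
  ci <- function(x) {
    se <- stats::sd(x) / sqrt(length(x))
    m <- mean(x)
    c(mean = m, lower = m - stats::qt(0.975, length(x) - 1) * se,
      upper = m + stats::qt(0.975, length(x) - 1) * se)
  }
  diffs <- wide$rating.min_noxious - wide$rating.max_warm
  list(means = rbind(max_warm = ci(wide$rating.max_warm),
                     min_noxious = ci(wide$rating.min_noxious)),
       subject_means = wide,
       bf = bf_ttest_paired(diffs = diffs))
}

task_pairs <- function(tasks) {
  pr <- utils::combn(tasks, 2)
  data.frame(task1 = pr[1, ], task2 = pr[2, ])
}

#' Run the full group analysis
#'
#' End-to-end pipeline: exclusion rules, per-subject measures (d', meta-d',
#' efficiency ratio and difference, proportion correct, mean confidence),
#' pairwise modality comparisons (paired JZS t-test Bayes factors on every
#' measure), cross-task Pearson correlations with one-sided (positive)
#' stretched-beta Bayes factors for d', meta-d', efficiency and mean
#' confidence, Steiger's Z comparisons among the three efficiency
#' correlations, the hierarchical Bayesian efficiency model, and the
#' manipulation check. Deterministic given `config$seed`. Stage failures are
#' carried as flagged entries rather than dropped silently.
#'
#' @param trials Trial data frame or `study_dataset`.
#' @param ratings Rating data frame (optional; enables the manipulation
#'   check).
#' @param config An [analysis_config()].
#' @return A `report_bundle` list: `subject_measures`, `comparisons`,
#'   `correlations`, `steiger`, `hierarchical`, `manipulation`, `exclusions`
#'   and `provenance`.
#' @export
run_full_analysis <- function(trials, ratings = NULL,
                              config = analysis_config()) {
  if (inherits(trials, "study_dataset")) {
    if (is.null(ratings)) ratings <- trials$ratings
    trials <- trials$trials
  }
  set.seed(config$seed)
  excl <- apply_exclusions(trials, ratings, config)
  analysed <- excl$trials[!excl$trials$is_practice, ]
  tasks <- sort(unique(analysed$task))
  subjects <- unique(analysed$subject)

  measures <- do.call(rbind, lapply(subjects, function(subj) {
    do.call(rbind, lapply(tasks, function(task) {
      sub <- analysed[analysed$subject == subj & analysed$task == task, ]
      row <- tryCatch(
        subject_measures(sub, K = config$K, method = config$fit_method,
                         mcmc = config$mcmc),
        error = function(e) data.frame(
          pct_correct = NA_real_, d_prime = NA_real_, meta_d = NA_real_,
          efficiency_ratio = NA_real_, efficiency_diff = NA_real_,
          mean_confidence = NA_real_, converged = FALSE))
      cbind(data.frame(subject = subj, task = task), row)
    }))
  }))

  measure_names <- c("pct_correct", "d_prime", "meta_d", "efficiency_ratio",
                     "efficiency_diff", "mean_confidence")
  pairs <- task_pairs(tasks)
  wide <- function(m) {
    w <- stats::reshape(measures[c("subject", "task", m)], idvar = "subject",
                        timevar = "task", direction = "wide")
    stats::setNames(w[-1], sub(paste0("^", m, "\\."), "", names(w)[-1]))
  }
  comparisons <- do.call(rbind, lapply(measure_names, function(m) {
    w <- wide(m)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
      d <- w[[pairs$task1[j]]] - w[[pairs$task2[j]]]
      d <- d[!is.na(d)]
      bf <- tryCatch(bf_ttest_paired(diffs = d)$bf, error = function(e) NA_real_)
      data.frame(measure = m, task1 = pairs$task1[j], task2 = pairs$task2[j],
                 mean_diff = mean(d), bf10 = bf)
    }))
  }))

  corr_measures <- c("d_prime", "meta_d", "efficiency_ratio",
                     "mean_confidence")
  correlations <- do.call(rbind, lapply(corr_measures, function(m) {
    w <- wide(m)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
      ok <- stats::complete.cases(w[[pairs$task1[j]]], w[[pairs$task2[j]]])
      r <- stats::cor(w[[pairs$task1[j]]][ok], w[[pairs$task2[j]]][ok])
      bf <- tryCatch(
        bf_correlation(r, sum(ok), side = "positive")$bf,
        error = function(e) NA_real_)
      data.frame(measure = m, task1 = pairs$task1[j], task2 = pairs$task2[j],
                 r = r, n = sum(ok), bf_positive = bf)
    }))
  }))

  steiger <- NULL
  if (length(tasks) == 3) {
    eff <- correlations[correlations$measure == "efficiency_ratio", ]
    rr <- function(a, b) {
      hit <- (eff$task1 == a & eff$task2 == b) |
        (eff$task1 == b & eff$task2 == a)
      eff$r[hit]
    }
    n <- eff$n[1]
    combos <- utils::combn(seq_len(nrow(pairs)), 2)
    steiger <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      p1 <- pairs[combos[1, j], ]; p2 <- pairs[combos[2, j], ]
      shared <- intersect(unlist(p1), unlist(p2))
      others <- setdiff(unlist(c(p1, p2)), shared)
      st <- steiger_overlapping(rr(p1$task1, p1$task2),
                                rr(p2$task1, p2$task2),
                                rr(others[1], others[2]), n)
      data.frame(cor1 = paste(p1$task1, p1$task2, sep = "-"),
                 cor2 = paste(p2$task1, p2$task2, sep = "-"),
                 z = st$z, p = st$p)
    }))
  }

  hier <- NULL
  if (isTRUE(config$hierarchical) && length(tasks) >= 2) {
    counts <- lapply(subjects, function(subj)
      stats::setNames(lapply(tasks, function(task)
        collate_type2_counts(
          analysed[analysed$subject == subj & analysed$task == task, ],
          K = config$K, padding = "none")), tasks))
    hier <- tryCatch(fit_hierarchical_efficiency(counts, mcmc = config$mcmc),
                     error = function(e) list(error = conditionMessage(e)))
  }

  manip <- if (!is.null(excl$ratings) && nrow(excl$ratings))
    tryCatch(manipulation_check(excl$ratings),
             error = function(e) list(error = conditionMessage(e)))

  structure(list(
    subject_measures = measures,
    comparisons = comparisons,
    correlations = correlations,
    steiger = steiger,
    hierarchical = hier,
    manipulation = manip,
    exclusions = excl$audit,
    provenance = list(
      seed = config$seed, config = unclass(config)[setdiff(
        names(unclass(config)), "mcmc")],
      mcmc = unclass(config$mcmc),
      package_version = as.character(utils::packageVersion("metaconf")))),
    class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  ms <- x$subject_measures
  cat(sprintf("Report bundle: %d subjects x %d tasks\n",
              length(unique(ms$subject)), length(unique(ms$task))))
  agg <- stats::aggregate(
    ms[c("pct_correct", "d_prime", "meta_d", "efficiency_ratio",
         "mean_confidence")], by = list(task = ms$task), mean, na.rm = TRUE)
  print(agg, row.names = FALSE, digits = 3)
  cat("\nCross-task correlations (positive-sided BF):\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  if (!is.null(x$steiger)) {
    cat("\nSteiger comparisons of efficiency correlations:\n")
    print(x$steiger, row.names = FALSE, digits = 3)
  }
  if (inherits(x$hierarchical, "hierarchical_posterior")) {
    cat("\n"); print(x$hierarchical)
  }
  if (!is.null(x$manipulation$bf))
    cat(sprintf("\nManipulation check BF10 = %.4g\n", x$manipulation$bf$bf))
  if (nrow(x$exclusions))
    cat(sprintf("\n%d subject(s) excluded\n", nrow(x$exclusions)))
  invisible(x)
}

#' Write a report bundle as JSON
#'
#' Serialises every statistic in the bundle together with its prior and
#' sampler settings so that each reported number is traceable to the
#' configuration and seed.
#'
#' @param bundle A `report_bundle` from [run_full_analysis()].
#' @param path Output path.
#' @export
write_report_json <- function(bundle, path) {
  out <- list(
    subject_measures = bundle$subject_measures,
    comparisons = bundle$comparisons,
    correlations = bundle$correlations,
    steiger = bundle$steiger,
    hierarchical = if (inherits(bundle$hierarchical,
                                "hierarchical_posterior"))
      list(pairs = bundle$hierarchical$pairs,
           rhat = bundle$hierarchical$diagnostics$rhat)
    else bundle$hierarchical,
    manipulation = if (!is.null(bundle$manipulation$bf))
      list(means = as.data.frame(bundle$manipulation$means),
           bf10 = bundle$manipulation$bf$bf,
           prior = bundle$manipulation$bf$prior)
    else bundle$manipulation,
    exclusions = bundle$exclusions,
    provenance = bundle$provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Staircase convergence diagnostics
#'
#' Per subject-task summary of the adaptive track: proportion correct over
#' analysed trials, mean and SD of the analysed test intensity, and the
#' proportion of analysed trials at the intensity cap.
#'
#' @param trials Trial data frame or `study_dataset`.
#' @return Data frame with one row per subject-task.
#' @export
staircase_diagnostics <- function(trials) {
  if (inherits(trials, "study_dataset")) trials <- trials$trials
  analysed <- trials[!trials$is_practice, ]
  do.call(rbind, lapply(split(analysed,
                              analysed[c("subject", "task")], drop = TRUE),
    function(sub) data.frame(
      subject = sub$subject[1], task = sub$task[1],
      pct_correct = mean(sub$correct),
      mean_intensity = mean(sub$test_intensity),
      sd_intensity = stats::sd(sub$test_intensity),
      pct_at_cap = mean(sub$test_intensity == max(trials$test_intensity[
        trials$task == sub$task[1]])))))
}
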