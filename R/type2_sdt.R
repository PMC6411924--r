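#' Tabulate confidence counts for type-2 SDT analysis
#'
#' Collapses a single subject-task trial log into the confidence-count table
#' that is the sufficient statistic for all signal-detection fits: counts
#' indexed by stimulus class (test stimulus in interval 1 or 2), response
#' (chosen interval) and confidence level 1..K.
#'
#' @param trials Data frame with columns `test_interval` (1 or 2),
#'   `response_interval` (1 or 2) and `confidence` (integer 1..K), one row per
#'   analysed trial (practice trials removed upstream). Rows with missing
#'   response or confidence are dropped and reported via the `n_dropped`
#'   attribute.
#' @param K Number of confidence levels (4 in the reference design).
#' @param padding `"none"` (raw integer counts, required by the Bayesian fit)
#'   or `"uniform"` (adds 1/(2K) to every cell, the convention used for
#'   maximum-likelihood fitting and rate estimation so that no observed rate
#'   is exactly 0 or 1).
#' @return A `type2_counts` object: a 2 x 2 x K array with dimensions
#'   stimulus (`S1`, `S2`), response (`R1`, `R2`) and confidence (`1`..`K`).
#' @export
collate_type2_counts <- function(trials, K = 4L,
                                 padding = c("none", "uniform")) {
  padding <- match.arg(padding)
  K <- as.integer(K)
  req <- c("test_interval", "response_interval", "confidence")
  missing_cols <- setdiff(req, names(trials))
  if (length(missing_cols))
    stop("trials is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(trials[req])
  n_dropped <- sum(!keep)
  trials <- trials[keep, , drop = FALSE]
  if (nrow(trials) == 0L) stop("no analysable trials", call. = FALSE)
  if (any(!trials$confidence %in% seq_len(K)))
    stop("confidence ratings outside 1..", K, call. = FALSE)
  if (any(!trials$test_interval %in% 1:2) ||
      any(!trials$response_interval %in% 1:2))
    stop("test_interval and response_interval must be 1 or 2", call. = FALSE)
  counts <- array(0, dim = c(2L, 2L, K),
                  dimnames = list(stimulus = c("S1", "S2"),
                                  response = c("R1", "R2"),
                                  confidence = seq_len(K)))
  tab <- table(factor(trials$test_interval, 1:2),
               factor(trials$response_interval, 1:2),
               factor(trials$confidence, seq_len(K)))
  counts[] <- as.numeric(tab)
  if (padding == "uniform") counts <- counts + 1 / (2 * K)
  structure(counts, class = c("type2_counts", "array"),
            K = K, padding = padding, n_dropped = n_dropped)
}

#' @export
print.type2_counts <- function(x, ...) {
  cat("Type-2 confidence counts (K =", attr(x, "K"),
      ", padding =", attr(x, "padding"), ")\n")
  print(unclass(x)[, , , drop = FALSE])
  invisible(x)
}

pad_counts <- function(counts) {
  if (identical(attr(counts, "padding"), "uniform")) return(counts)
  K <- attr(counts, "K")
  out <- counts + 1 / (2 * K)
  attr(out, "padding") <- "uniform"
  out
}

#' Type-1 sensitivity and criterion from response rates
#'
#' Equal-variance Gaussian signal detection: with H = P(R1 | S1) and
#' F = P(R1 | S2), d' = z(H) - z(F) and c = -(z(H) + z(F)) / 2, where z is the
#' standard normal quantile function.
#'
#' @param H,F Response rates strictly inside (0, 1).
#' @return List with `d_prime` and `criterion_c`.
#' @export
type1_sdt <- function(H, F) {
  if (any(c(H, F) <= 0) || any(c(H, F) >= 1))
    stop("rates must lie strictly in (0, 1); apply a padding policy first",
         call. = FALSE)
  zH <- stats::qnorm(unname(H))
  zF <- stats::qnorm(unname(F))
  list(d_prime = zH - zF, criterion_c = -(zH + zF) / 2)
}

#' Type-1 estimates from a confidence-count table
#'
#' Collapses the table over confidence to the 2 x 2 type-1 table and applies
#' [type1_sdt()]. Rates are always computed from uniformly padded counts so
#' that empty cells cannot produce infinite z-scores.
#'
#' @param counts A `type2_counts` object containing both stimulus classes.
#' @return List with `d_prime` and `criterion_c`.
#' @export
estimate_type1 <- function(counts) {
  stopifnot(inherits(counts, "type2_counts"))
  p <- pad_counts(counts)
  t1 <- apply(p, c(1, 2), sum)
  if (any(rowSums(t1) == 0))
    stop("both stimulus classes must be present", call. = FALSE)
  type1_sdt(H = t1["S1", "R1"] / sum(t1["S1", ]),
            F = t1["S2", "R1"] / sum(t1["S2", ]))
}

# Meta-level axis convention used throughout: S1 has mean +d/2, S2 has mean
# -d/2, response R1 iff the decision variable exceeds the criterion. The K-1
# type-2 criteria on the R1 side increase away from the meta-level criterion;
# the K-1 on the R2 side decrease away from it. `t2_criteria` is stored as a
# single strictly increasing vector of length 2(K-1): the first K-1 entries
# lie below the meta criterion (R2 side), the rest above it (R1 side).

meta_criterion <- function(meta_d, d_prime, criterion_c) {
  cprime <- if (abs(d_prime) > 1e-12) criterion_c / d_prime else 0
  cprime * meta_d
}

# P(confidence = k | stimulus, response) under the meta-level observer, as a
# 2 x 2 x K array; also returns type-1 response probabilities from (d', c).
type2_cond_probs <- function(d_prime, criterion_c, meta_d, t2_criteria, K) {
  mc <- meta_criterion(meta_d, d_prime, criterion_c)
  r2c <- t2_criteria[seq_len(K - 1)]
  r1c <- t2_criteria[K:(2 * K - 2)]
  if (any(diff(t2_criteria) <= 0) || any(r2c > mc) || any(r1c < mc))
    stop("type-2 criteria must be strictly increasing around the meta-level criterion",
         call. = FALSE)
  mu <- c(S1 = meta_d / 2, S2 = -meta_d / 2)
  cond <- array(NA_real_, dim = c(2L, 2L, K),
                dimnames = list(stimulus = c("S1", "S2"),
                                response = c("R1", "R2"),
                                confidence = seq_len(K)))
  cuts_r1 <- c(mc, r1c, Inf)              # ascending; conf k in (cuts[k], cuts[k+1])
  cuts_r2 <- c(mc, rev(r2c), -Inf)        # descending; conf k in (cuts[k+1], cuts[k])
  for (s in 1:2) {
    p_r1 <- diff(stats::pnorm(cuts_r1 - mu[s]))
    p_r2 <- -diff(stats::pnorm(cuts_r2 - mu[s]))
    cond[s, "R1", ] <- p_r1 / sum(p_r1)
    cond[s, "R2", ] <- p_r2 / sum(p_r2)
  }
  pR1 <- c(S1 = stats::pnorm(criterion_c, mean = d_prime / 2, lower.tail = FALSE),
           S2 = stats::pnorm(criterion_c, mean = -d_prime / 2, lower.tail = FALSE))
  list(cond = cond, p_response = rbind(S1 = c(R1 = pR1[["S1"]], R2 = 1 - pR1[["S1"]]),
                                       S2 = c(R1 = pR1[["S2"]], R2 = 1 - pR1[["S2"]])))
}

#' Predicted joint probabilities of the type-2 SDT model
#'
#' Joint probability of (response, confidence) for each stimulus class under
#' the meta-d' model: type-1 response probabilities follow the equal-variance
#' Gaussian observer (d', c); confidence, conditional on stimulus and
#' response, follows a meta-level observer with sensitivity `meta_d` whose
#' type-1 criterion sits at the same relative position c' = c/d'. Each
#' (stimulus, response) cell's confidence distribution sums to the type-1
#' probability of that cell, so each stimulus class sums to 1.
#'
#' @param d_prime Type-1 sensitivity.
#' @param criterion_c Type-1 criterion.
#' @param meta_d Meta-level sensitivity (type-1 units).
#' @param t2_criteria Strictly increasing vector of length 2(K-1); the first
#'   K-1 entries must lie below the meta-level criterion, the rest above it.
#' @param K Number of confidence levels.
#' @return A 2 x 2 x K array of joint probabilities (stimulus x response x
#'   confidence).
#' @export
model_predicted_probs <- function(d_prime, criterion_c, meta_d, t2_criteria,
                                  K = length(t2_criteria) / 2 + 1) {
  K <- as.integer(K)
  stopifnot(length(t2_criteria) == 2 * (K - 1))
  parts <- type2_cond_probs(d_prime, criterion_c, meta_d, t2_criteria, K)
  probs <- parts$cond
  for (s in 1:2) for (r in 1:2)
    probs[s, r, ] <- probs[s, r, ] * parts$p_response[s, r]
  probs
}

# negative log-likelihood of confidence counts conditional on (stimulus,
# response); the type-1 term is constant because (d', c) are fixed
neg_loglik_meta <- function(theta, counts, d_prime, criterion_c, K) {
  meta_d <- theta[1]
  mc <- meta_criterion(meta_d, d_prime, criterion_c)
  inc_r2 <- exp(theta[2:K])
  inc_r1 <- exp(theta[(K + 1):(2 * K - 1)])
  t2 <- c(mc - rev(cumsum(inc_r2)), mc + cumsum(inc_r1))
  parts <- try(type2_cond_probs(d_prime, criterion_c, meta_d, t2, K),
               silent = TRUE)
  if (inherits(parts, "try-error")) return(1e10)
  ll <- sum(counts * log(pmax(parts$cond, 1e-300)))
  if (!is.finite(ll)) return(1e10)
  -ll
}

theta_to_t2 <- function(theta, d_prime, criterion_c, K) {
  mc <- meta_criterion(theta[1], d_prime, criterion_c)
  c(mc - rev(cumsum(exp(theta[2:K]))),
    mc + cumsum(exp(theta[(K + 1):(2 * K - 1)])))
}

init_theta <- function(counts, d_prime, K) {
  # start at meta_d = d' with criterion spacing from the marginal confidence
  # distribution: increments at roughly the empirical type-2 quantiles
  conf_marg <- apply(counts, 3, sum)
  p <- (cumsum(conf_marg) / sum(conf_marg))[seq_len(K - 1)]
  q <- stats::qnorm(pmin(pmax(p, 0.05), 0.95))
  inc <- pmax(diff(c(0, abs(q) / 2 + 0.2)), 0.1)
  c(d_prime, log(rev(inc)), log(inc))
}

#' Maximum-likelihood meta-d' fit
#'
#' Fits the meta-d' model of Maniscalco and Lau by maximising the multinomial
#' log-likelihood of confidence counts conditional on stimulus and response,
#' over meta-d' and the 2(K-1) type-2 criteria, with the type-1 parameters
#' (d', c) fixed at their [estimate_type1()] values and the meta-level type-1
#' criterion fixed at the same relative position c' = c/d'. Criterion ordering
#' is enforced by optimising log-spaced increments with a bounded
#' quasi-Newton method (L-BFGS-B), with a Nelder-Mead refinement fallback.
#'
#' @param counts A `type2_counts` table; uniform padding (1/(2K) per cell) is
#'   applied if the table is unpadded.
#' @return An object of class `sdt_estimate` with elements `d_prime`,
#'   `criterion_c`, `relative_criterion`, `meta_d`, `t2_criteria`,
#'   `efficiency_ratio` (meta-d'/d'), `efficiency_diff` (meta-d' - d'),
#'   `log_likelihood`, `method` and `converged`.
#' @export
fit_meta_d_mle <- function(counts) {
  stopifnot(inherits(counts, "type2_counts"))
  K <- attr(counts, "K")
  counts <- pad_counts(counts)
  t1 <- estimate_type1(counts)
  theta0 <- init_theta(counts, t1$d_prime, K)
  fit <- stats::optim(theta0, neg_loglik_meta, counts = counts,
                      d_prime = t1$d_prime, criterion_c = t1$criterion_c,
                      K = K, method = "L-BFGS-B",
                      lower = c(-10, rep(-8, 2 * K - 2)),
                      upper = c(10, rep(3, 2 * K - 2)),
                      control = list(maxit = 500))
  refine <- stats::optim(fit$par, neg_loglik_meta, counts = counts,
                         d_prime = t1$d_prime, criterion_c = t1$criterion_c,
                         K = K, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
  if (refine$value < fit$value) fit <- refine
  meta_d <- fit$par[1]
  used_levels <- sum(apply(counts, 3, sum) > 1)  # padded cells contribute < 1
  new_sdt_estimate(
    d_prime = t1$d_prime, criterion_c = t1$criterion_c, meta_d = meta_d,
    t2_criteria = theta_to_t2(fit$par, t1$d_prime, t1$criterion_c, K),
    log_likelihood = -fit$value, method = "MLE",
    converged = fit$convergence == 0 && used_levels > 1)
}

new_sdt_estimate <- function(d_prime, criterion_c, meta_d, t2_criteria,
                             log_likelihood, method, converged,
                             posterior_summary = NULL, diagnostics = NULL) {
  d_prime <- unname(d_prime); criterion_c <- unname(criterion_c)
  meta_d <- unname(meta_d)
  structure(
    list(d_prime = d_prime, criterion_c = criterion_c,
         relative_criterion = if (abs(d_prime) > 1e-12) criterion_c / d_prime else NA_real_,
         meta_d = meta_d, t2_criteria = t2_criteria,
         efficiency_ratio = meta_d / d_prime,
         efficiency_diff = meta_d - d_prime,
         log_likelihood = log_likelihood, method = method,
         converged = converged, posterior_summary = posterior_summary,
         diagnostics = diagnostics),
    class = "sdt_estimate")
}

#' @export
print.sdt_estimate <- function(x, ...) {
  cat(sprintf("meta-d' fit (%s)%s\n", x$method,
              if (isTRUE(x$converged)) "" else "  [not converged]"))
  cat(sprintf("  d' = %.3f   c = %.3f   meta-d' = %.3f\n",
              x$d_prime, x$criterion_c, x$meta_d))
  cat(sprintf("  efficiency: meta-d'/d' = %.3f   meta-d' - d' = %.3f\n",
              x$efficiency_ratio, x$efficiency_diff))
  invisible(x)
}

#' MCMC settings for the Bayesian fits
#'
#' @param n_chains Number of chains.
#' @param n_adapt Adaptation iterations.
#' @param n_burnin Burn-in iterations per chain.
#' @param n_iter Kept iterations per chain.
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 3L, n_adapt = 500L, n_burnin = 1000L,
                          n_iter = 1000L, seed = 1L) {
  structure(list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
                 n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 seed = as.integer(seed)), class = "mcmc_settings")
}

jags_inits <- function(mcmc) {
  lapply(seq_len(mcmc$n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (mcmc$seed * 1009L + ch * 7919L) %% 2147483647L))
}

single_subject_jags_model <- "
model {
  for (s in 1:2) {
    n_r1[s, 1:K] ~ dmulti(p_r1[s, 1:K], tot_r1[s])
    n_r2[s, 1:K] ~ dmulti(p_r2[s, 1:K], tot_r2[s])
  }
  log_ratio ~ dnorm(0, 1)
  meta_d <- exp(log_ratio) * d1
  mc <- cprime * meta_d
  mu[1] <-  meta_d / 2
  mu[2] <- -meta_d / 2
  for (j in 1:(K - 1)) {
    inc_r1[j] ~ dnorm(0, 1) T(0, )
    inc_r2[j] ~ dnorm(0, 1) T(0, )
  }
  cut_r1[1] <- mc
  cut_r2[1] <- mc
  for (j in 2:K) {
    cut_r1[j] <- cut_r1[j - 1] + inc_r1[j - 1]
    cut_r2[j] <- cut_r2[j - 1] - inc_r2[j - 1]
  }
  for (s in 1:2) {
    for (k in 1:(K - 1)) {
      q_r1[s, k] <- phi(cut_r1[k + 1] - mu[s]) - phi(cut_r1[k] - mu[s])
      q_r2[s, k] <- phi(cut_r2[k] - mu[s]) - phi(cut_r2[k + 1] - mu[s])
    }
    q_r1[s, K] <- 1 - phi(cut_r1[K] - mu[s])
    q_r2[s, K] <- phi(cut_r2[K] - mu[s])
    for (k in 1:K) {
      qq_r1[s, k] <- max(q_r1[s, k], 1e-10)
      qq_r2[s, k] <- max(q_r2[s, k], 1e-10)
    }
    for (k in 1:K) {
      p_r1[s, k] <- qq_r1[s, k] / sum(qq_r1[s, 1:K])
      p_r2[s, k] <- qq_r2[s, k] / sum(qq_r2[s, 1:K])
    }
  }
}
"

#' Single-subject Bayesian meta-d' fit
#'
#' Same conditional-multinomial likelihood as [fit_meta_d_mle()], with a
#' Normal(0, 1) prior on log(meta-d'/d'), half-Normal(1) priors on the spacing
#' of the ordered type-2 criteria, and the type-1 parameters fixed at their
#' [estimate_type1()] values. Sampled with JAGS.
#'
#' @param counts A `type2_counts` table of raw (unpadded) counts; the
#'   multinomial likelihood handles zeros.
#' @param mcmc An [mcmc_settings()] object.
#' @return An `sdt_estimate` with `posterior_summary` (mean, SD, 2.5\% and
#'   97.5\% quantiles for meta-d' and the efficiency ratio) and convergence
#'   diagnostics (split-chain R-hat); `converged` is `FALSE` when R-hat
#'   exceeds 1.05.
#' @export
fit_meta_d_bayes <- function(counts, mcmc = mcmc_settings()) {
  stopifnot(inherits(counts, "type2_counts"))
  if (identical(attr(counts, "padding"), "uniform"))
    stop("Bayesian fitting requires unpadded integer counts", call. = FALSE)
  K <- attr(counts, "K")
  t1 <- estimate_type1(counts)
  data <- list(
    K = K,
    n_r1 = rbind(counts["S1", "R1", ], counts["S2", "R1", ]),
    n_r2 = rbind(counts["S1", "R2", ], counts["S2", "R2", ]),
    tot_r1 = c(sum(counts["S1", "R1", ]), sum(counts["S2", "R1", ])),
    tot_r2 = c(sum(counts["S1", "R2", ]), sum(counts["S2", "R2", ])),
    d1 = abs(t1$d_prime) + 1e-6,
    cprime = t1$criterion_c / (abs(t1$d_prime) + 1e-6))
  model <- rjags::jags.model(textConnection(single_subject_jags_model),
                             data = data, inits = jags_inits(mcmc),
                             n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                             quiet = TRUE)
  update(model, mcmc$n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(model, c("meta_d", "log_ratio"),
                              n.iter = mcmc$n_iter, progress.bar = "none")
  draws_meta <- unlist(lapply(samp, function(m) m[, "meta_d"]))
  draws_lr <- unlist(lapply(samp, function(m) m[, "log_ratio"]))
  rhat <- tryCatch(
    max(coda::gelman.diag(samp, autoburnin = FALSE,
                          multivariate = FALSE)$psrf[, 1]),
    error = function(e) NA_real_)
  ratio_draws <- exp(draws_lr)
  post <- list(
    meta_d = c(mean = mean(draws_meta), sd = stats::sd(draws_meta),
               stats::quantile(draws_meta, c(0.025, 0.975))),
    efficiency_ratio = c(mean = mean(ratio_draws), sd = stats::sd(ratio_draws),
                         stats::quantile(ratio_draws, c(0.025, 0.975))))
  new_sdt_estimate(
    d_prime = t1$d_prime, criterion_c = t1$criterion_c,
    meta_d = mean(draws_meta), t2_criteria = NULL,
    log_likelihood = NA_real_, method = "Bayesian",
    converged = is.finite(rhat) && rhat < 1.05,
    posterior_summary = post,
    diagnostics = list(rhat = rhat, n_draws = length(draws_meta)))
}

#' Per-subject summary measures for one task
#'
#' Computes the per-subject, per-task measures used in group analyses:
#' proportion correct over analysed trials, d', meta-d', metacognitive
#' efficiency as ratio (meta-d'/d') and difference (meta-d' - d'), and
#' metacognitive bias as the mean confidence rating irrespective of accuracy.
#'
#' @param trials Trial data frame for one subject-task with practice removed;
#'   requires columns `correct` and `confidence` in addition to those needed
#'   by [collate_type2_counts()].
#' @param K Number of confidence levels.
#' @param method `"mle"` or `"bayes"`.
#' @param mcmc [mcmc_settings()], used when `method = "bayes"`.
#' @return A one-row data frame with columns `pct_correct`, `d_prime`,
#'   `meta_d`, `efficiency_ratio`, `efficiency_diff`, `mean_confidence` and
#'   `converged`.
#' @export
subject_measures <- function(trials, K = 4L, method = c("mle", "bayes"),
                             mcmc = mcmc_settings()) {
  method <- match.arg(method)
  counts <- collate_type2_counts(trials, K = K, padding = "none")
  fit <- if (method == "mle") fit_meta_d_mle(counts)
         else fit_meta_d_bayes(counts, mcmc = mcmc)
  eff_ratio <- if (method == "bayes")
    fit$posterior_summary$efficiency_ratio[["mean"]] else fit$efficiency_ratio
  data.frame(
    pct_correct = mean(trials$correct),
    d_prime = fit$d_prime,
    meta_d = fit$meta_d,
    efficiency_ratio = eff_ratio,
    efficiency_diff = fit$meta_d - fit$d_prime,
    mean_confidence = mean(trials$confidence),
    converged = fit$converged)
}
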