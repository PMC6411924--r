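# Gauss hypergeometric 2F1(1/2, 1/2; c; z) for z in [0, 1), c > 1.
# Terms are positive and the ratio between successive terms is < z, so plain
# forward summation is stable; the sum is bounded by 1/(1-z).
hyp2f1_half <- function(c_par, z) {
  if (z < 0 || z >= 1) stop("z must lie in [0, 1)", call. = FALSE)
  term <- 1
  total <- 1
  k <- 0
  repeat {
    term <- term * (0.5 + k)^2 / ((c_par + k) * (k + 1)) * z
    total <- total + term
    k <- k + 1
    if (term < total * 1e-15 || k > 1e5) break
  }
  total
}

# log of the exact sampling density of the Pearson correlation r given the
# population correlation rho, at sample size n (Fisher's 1915 distribution in
# hypergeometric form)
log_dens_r_given_rho <- function(r, rho, n) {
  log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5) +
    (n - 1) / 2 * log1p(-rho^2) + (n - 4) / 2 * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r) +
    log(hyp2f1_half(n - 0.5, (rho * r + 1) / 2))
}

# stretched beta(1/kappa, 1/kappa) prior density on (-1, 1); kappa = 1 is
# uniform
stretched_beta_density <- function(rho, kappa) {
  0.5 * stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa)
}

new_bf_result <- function(bf, side, prior, numerical_error) {
  structure(list(bf = bf, side = side, prior = prior,
                 numerical_error = numerical_error),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("Bayes factor (%s): %.4g  [prior: %s]\n", x$side, x$bf, x$prior))
  invisible(x)
}

#' Bayes factor for a Pearson correlation
#'
#' Evidence for a correlation versus the point null rho = 0, computed by
#' numerically integrating the exact sampling density of the observed
#' correlation coefficient against a stretched beta prior of width `kappa`
#' (`kappa = 1` is uniform on (-1, 1), the default used for one-sided tests of
#' a positive association, BF+0). One-sided versions restrict the prior to
#' the requested half-interval and renormalise it.
#'
#' @param r Observed Pearson correlation, |r| < 1.
#' @param n Sample size (>= 4).
#' @param side `"two-sided"`, `"positive"` (BF+0) or `"negative"` (BF-0).
#' @param kappa Stretched-beta prior width (> 0).
#' @return A `bf_result` with the Bayes factor, side, prior descriptor and
#'   estimated relative integration error.
#' @examples
#' bf_correlation(0.42, 36, side = "positive")  # approx 9.4
#' @export
bf_correlation <- function(r, n, side = c("two-sided", "positive", "negative"),
                           kappa = 1) {
  side <- match.arg(side)
  if (!is.finite(r) || abs(r) >= 1)
    stop("|r| must be < 1", call. = FALSE)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  lims <- switch(side, "two-sided" = c(-1, 1), positive = c(0, 1),
                 negative = c(-1, 0))
  renorm <- if (side == "two-sided") 1 else 2  # symmetric prior: half-mass = 1/2
  integrand <- function(rho)
    exp(log_dens_r_given_rho(r, rho, n) - log_dens_r_given_rho(r, 0, n)) *
      stretched_beta_density(rho, kappa) * renorm
  quad <- stats::integrate(Vectorize(integrand), lims[1], lims[2],
                           rel.tol = 1e-8, abs.tol = 0, subdivisions = 500L)
  new_bf_result(bf = quad$value, side = side,
                prior = sprintf("stretched beta, width %g%s", kappa,
                                if (side != "two-sided")
                                  paste0(", restricted ", side) else ""),
                numerical_error = quad$abs.error / max(quad$value, 1e-300))
}

#' JZS Bayes factor for a paired t-test
#'
#' Jeffreys-Zellner-Siow Bayes factor (BF10) for a one-sample/paired design:
#' a Cauchy prior with scale `scale` on the standardised effect size,
#' marginalised by one-dimensional quadrature over the g-prior
#' (InverseGamma(1/2, scale^2/2)) representation.
#'
#' @param diffs Vector of paired differences; alternatively supply `t` and
#'   `n` directly.
#' @param t Precomputed t statistic (used with `n` when `diffs` is missing).
#' @param n Number of pairs.
#' @param scale Cauchy prior scale (default 0.707 = sqrt(2)/2).
#' @return A `bf_result`.
#' @examples
#' bf_ttest_paired(t = 5, n = 36)
#' @export
bf_ttest_paired <- function(diffs = NULL, t = NULL, n = NULL,
                            scale = sqrt(2) / 2) {
  if (!is.null(diffs)) {
    n <- length(diffs)
    if (n < 2) stop("need at least 2 pairs", call. = FALSE)
    if (stats::sd(diffs) == 0)
      stop("paired differences have zero variance", call. = FALSE)
    t <- mean(diffs) / (stats::sd(diffs) / sqrt(n))
  }
  if (is.null(t) || is.null(n))
    stop("supply either `diffs` or both `t` and `n`", call. = FALSE)
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  nu <- n - 1
  log_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  log_integrand <- function(g)
    -0.5 * log1p(n * g) -
      (nu + 1) / 2 * log1p(t^2 / ((1 + n * g) * nu)) +
      log(scale) - 0.5 * log(2 * pi) - 1.5 * log(g) - scale^2 / (2 * g) -
      log_null
  quad <- stats::integrate(function(g) exp(log_integrand(g)), 0, Inf,
                           rel.tol = 1e-8, subdivisions = 1000L)
  new_bf_result(bf = quad$value, side = "two-sided",
                prior = sprintf("Cauchy, scale %.3f", scale),
                numerical_error = quad$abs.error / max(quad$value, 1e-300))
}

#' Steiger's Z test for overlapping dependent correlations
#'
#' Compares two correlations r_jk and r_jh that share the variable j, using
#' Fisher z transforms and the pooled-estimate covariance of Steiger (1980):
#' with rbar = (r_jk + r_jh)/2,
#' psi = r_kh (1 - 2 rbar^2) - rbar^2 (1 - 2 rbar^2 - r_kh^2) / 2 and
#' s = psi / (1 - rbar^2)^2, the statistic is
#' Z = (z_jk - z_jh) sqrt((n - 3) / (2 - 2 s)), referred to the standard
#' normal (two-tailed).
#'
#' @param r_jk,r_jh The two correlations being compared (shared variable j).
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @return A `steiger_result` with `z`, `p` and the inputs.
#' @examples
#' steiger_overlapping(0.42, -0.04, 0.12, 36)  # Z approx 2.09
#' @export
steiger_overlapping <- function(r_jk, r_jh, r_kh, n) {
  rs <- c(r_jk, r_jh, r_kh)
  if (any(!is.finite(rs)) || any(abs(rs) >= 1))
    stop("all correlations must satisfy |r| < 1", call. = FALSE)
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  R <- matrix(c(1, r_jk, r_jh,
                r_jk, 1, r_kh,
                r_jh, r_kh, 1), 3, 3)
  if (det(R) < -1e-12)
    stop("correlation triple is not embeddable in a valid correlation matrix",
         call. = FALSE)
  z_jk <- atanh(r_jk)
  z_jh <- atanh(r_jh)
  rbar <- (r_jk + r_jh) / 2
  psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z_jk - z_jh) * sqrt((n - 3) / (2 - 2 * s))
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)),
                 inputs = list(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n)),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("Steiger's Z = %.3f, two-tailed p = %.4f  (n = %d)\n",
              x$z, x$p, x$inputs$n))
  invisible(x)
}

hierarchical_jags_model <- "
model {
  for (i in 1:N) {
    eta[i, 1:T] ~ dmnorm(zeros[1:T], TauW[1:T, 1:T])
    for (t in 1:T) {
      L[i, t] <- mu[t] + xi[t] * eta[i, t]
      metad[i, t] <- exp(L[i, t]) * d1[i, t]
      mc[i, t] <- cprime[i, t] * metad[i, t]
      muS[i, t, 1] <-  metad[i, t] / 2
      muS[i, t, 2] <- -metad[i, t] / 2
      for (j in 1:(K - 1)) {
        inc_r1[i, t, j] ~ dnorm(0, 1) T(0, )
        inc_r2[i, t, j] ~ dnorm(0, 1) T(0, )
      }
      cut_r1[i, t, 1] <- mc[i, t]
      cut_r2[i, t, 1] <- mc[i, t]
      for (j in 2:K) {
        cut_r1[i, t, j] <- cut_r1[i, t, j - 1] + inc_r1[i, t, j - 1]
        cut_r2[i, t, j] <- cut_r2[i, t, j - 1] - inc_r2[i, t, j - 1]
      }
      for (s in 1:2) {
        for (k in 1:(K - 1)) {
          q_r1[i, t, s, k] <- phi(cut_r1[i, t, k + 1] - muS[i, t, s]) -
                              phi(cut_r1[i, t, k] - muS[i, t, s])
          q_r2[i, t, s, k] <- phi(cut_r2[i, t, k] - muS[i, t, s]) -
                              phi(cut_r2[i, t, k + 1] - muS[i, t, s])
        }
        q_r1[i, t, s, K] <- 1 - phi(cut_r1[i, t, K] - muS[i, t, s])
        q_r2[i, t, s, K] <- phi(cut_r2[i, t, K] - muS[i, t, s])
        for (k in 1:K) {
          qq_r1[i, t, s, k] <- max(q_r1[i, t, s, k], 1.0E-10)
          qq_r2[i, t, s, k] <- max(q_r2[i, t, s, k], 1.0E-10)
        }
        for (k in 1:K) {
          p_r1[i, t, s, k] <- qq_r1[i, t, s, k] / sum(qq_r1[i, t, s, 1:K])
          p_r2[i, t, s, k] <- qq_r2[i, t, s, k] / sum(qq_r2[i, t, s, 1:K])
        }
        n_r1[i, t, s, 1:K] ~ dmulti(p_r1[i, t, s, 1:K], tot_r1[i, t, s])
        n_r2[i, t, s, 1:K] ~ dmulti(p_r2[i, t, s, 1:K], tot_r2[i, t, s])
      }
    }
  }
  for (t in 1:T) {
    mu[t] ~ dnorm(0, 1)
    xi[t] ~ dnorm(0, 1) T(0, )
  }
  TauW[1:T, 1:T] ~ dwish(I3[1:T, 1:T], Twish)
  SigmaW[1:T, 1:T] <- inverse(TauW[1:T, 1:T])
  for (a in 1:T) {
    sigma[a] <- xi[a] * sqrt(SigmaW[a, a])
    for (b in 1:T) {
      rho[a, b] <- SigmaW[a, b] / sqrt(SigmaW[a, a] * SigmaW[b, b])
    }
  }
}
"

#' Hierarchical Bayesian cross-task correlation of metacognitive efficiency
#'
#' Fits the group model in which each subject's log metacognitive efficiency
#' log(meta-d'/d') across tasks follows a multivariate normal with task-level
#' means, SDs and a correlation matrix, while each subject-task's confidence
#' counts follow the meta-d' conditional multinomial likelihood with type-1
#' parameters fixed at their [estimate_type1()] values. Uncertainty in the
#' subject-level efficiencies therefore propagates into the posterior of the
#' cross-task correlations. The covariance prior is a scaled inverse Wishart:
#' Wishart(I, T+1) on the precision of the latent (unit-scale) subject
#' effects, whose implied marginal prior on each pairwise correlation is
#' uniform on (-1, 1), with separate half-Normal(1) task scale parameters.
#' The separate scales avoid the small-variance bias toward zero correlation
#' of a plain inverse-Wishart covariance prior. Task means have Normal(0, 1)
#' priors.
#'
#' @param counts_by_subject_task List over subjects; each element a named list
#'   of unpadded `type2_counts`, one per task, with identical task names for
#'   every subject.
#' @param mcmc [mcmc_settings()].
#' @return A `hierarchical_posterior`: posterior draws of the correlation
#'   matrix (`rho_draws`, draws x T x T), task means and SDs, a per-pair
#'   summary table (`pairs`: posterior mean, 95\% credible interval, and a
#'   significance flag set when the interval excludes zero), and R-hat
#'   diagnostics.
#' @export
fit_hierarchical_efficiency <- function(counts_by_subject_task,
                                        mcmc = mcmc_settings()) {
  N <- length(counts_by_subject_task)
  if (N < 2) stop("need at least 2 subjects", call. = FALSE)
  tasks <- names(counts_by_subject_task[[1]])
  T <- length(tasks)
  for (sub in counts_by_subject_task)
    if (!identical(sort(names(sub)), sort(tasks)))
      stop("every subject must have counts for the same tasks", call. = FALSE)
  K <- attr(counts_by_subject_task[[1]][[1]], "K")
  n_r1 <- array(0, c(N, T, 2, K)); n_r2 <- array(0, c(N, T, 2, K))
  tot_r1 <- array(0, c(N, T, 2)); tot_r2 <- array(0, c(N, T, 2))
  d1 <- matrix(0, N, T); cprime <- matrix(0, N, T)
  for (i in seq_len(N)) for (t in seq_len(T)) {
    cts <- counts_by_subject_task[[i]][[tasks[t]]]
    if (identical(attr(cts, "padding"), "uniform"))
      stop("hierarchical fitting requires unpadded counts", call. = FALSE)
    t1 <- estimate_type1(cts)
    d1[i, t] <- abs(t1$d_prime) + 1e-6
    cprime[i, t] <- t1$criterion_c / d1[i, t]
    for (s in 1:2) {
      n_r1[i, t, s, ] <- cts[s, "R1", ]; tot_r1[i, t, s] <- sum(cts[s, "R1", ])
      n_r2[i, t, s, ] <- cts[s, "R2", ]; tot_r2[i, t, s] <- sum(cts[s, "R2", ])
    }
  }
  data <- list(N = N, T = T, K = K, n_r1 = n_r1, n_r2 = n_r2,
               tot_r1 = tot_r1, tot_r2 = tot_r2, d1 = d1, cprime = cprime,
               I3 = diag(T), Twish = T + 1, zeros = rep(0, T))
  model <- rjags::jags.model(textConnection(hierarchical_jags_model),
                             data = data, inits = jags_inits(mcmc),
                             n.chains = mcmc$n_chains, n.adapt = mcmc$n_adapt,
                             quiet = TRUE)
  update(model, mcmc$n_burnin, progress.bar = "none")
  samp <- rjags::coda.samples(model, c("rho", "mu", "sigma"),
                              n.iter = mcmc$n_iter, progress.bar = "none")
  mat <- do.call(rbind, lapply(samp, as.matrix))
  n_draws <- nrow(mat)
  rho_draws <- array(NA_real_, c(n_draws, T, T))
  for (a in seq_len(T)) for (b in seq_len(T))
    rho_draws[, a, b] <- mat[, sprintf("rho[%d,%d]", a, b)]
  mu_draws <- mat[, sprintf("mu[%d]", seq_len(T)), drop = FALSE]
  sigma_draws <- mat[, sprintf("sigma[%d]", seq_len(T)), drop = FALSE]
  colnames(mu_draws) <- colnames(sigma_draws) <- tasks
  pr <- utils::combn(T, 2)
  pairs <- data.frame(
    task1 = tasks[pr[1, ]], task2 = tasks[pr[2, ]],
    rho_mean = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
    significant = NA)
  for (j in seq_len(ncol(pr))) {
    dr <- rho_draws[, pr[1, j], pr[2, j]]
    ci <- stats::quantile(dr, c(0.025, 0.975))
    pairs$rho_mean[j] <- mean(dr)
    pairs$ci_lower[j] <- ci[1]; pairs$ci_upper[j] <- ci[2]
    pairs$significant[j] <- ci[1] > 0 || ci[2] < 0
  }
  offdiag <- sprintf("rho[%d,%d]", pr[1, ], pr[2, ])
  rhat <- tryCatch({
    sub <- lapply(samp, function(m) m[, c(offdiag,
                                          sprintf("mu[%d]", seq_len(T)))])
    max(coda::gelman.diag(coda::as.mcmc.list(sub), autoburnin = FALSE,
                          multivariate = FALSE)$psrf[, 1])
  }, error = function(e) NA_real_)
  structure(list(tasks = tasks, rho_draws = rho_draws, mu_draws = mu_draws,
                 sigma_draws = sigma_draws, pairs = pairs,
                 diagnostics = list(rhat = rhat, n_draws = n_draws),
                 converged = is.finite(rhat) && rhat < 1.05),
            class = "hierarchical_posterior")
}

#' @export
print.hierarchical_posterior <- function(x, ...) {
  cat("Hierarchical cross-task correlation of log metacognitive efficiency\n")
  print(x$pairs, row.names = FALSE, digits = 3)
  cat(sprintf("max split-chain R-hat: %.3f (%d draws)\n",
              x$diagnostics$rhat, x$diagnostics$n_draws))
  invisible(x)
}

#' Sequential Bayes-factor stopping rule
#'
#' Implements the sequential design in which Bayes factors for a set of
#' monitored tests are evaluated at a minimum sample size and after each
#' additional batch of participants; sampling stops at the first checkpoint
#' where every monitored Bayes factor is decisive, i.e. above `upper` or
#' below `lower`.
#'
#' @param bf_by_checkpoint List of numeric vectors (one per checkpoint, in
#'   order) holding the monitored Bayes factors, or a matrix with one row per
#'   checkpoint.
#' @param upper,lower Decision thresholds (defaults 3 and 1/3).
#' @param n_min Sample size at the first checkpoint (default 24).
#' @param step Participants added between checkpoints (default 4).
#' @return A `sequential_trace` with a per-checkpoint decision table and
#'   `n_final`, the sample size at the first stop (`NA` if never decisive).
#' @export
sequential_stopping <- function(bf_by_checkpoint, upper = 3, lower = 1 / 3,
                                n_min = 24L, step = 4L) {
  if (lower >= upper) stop("`lower` must be below `upper`", call. = FALSE)
  if (is.matrix(bf_by_checkpoint))
    bf_by_checkpoint <- asplit(bf_by_checkpoint, 1)
  m <- length(bf_by_checkpoint)
  ns <- n_min + step * (seq_len(m) - 1L)
  decisive <- vapply(bf_by_checkpoint, function(bfs)
    all(bfs > upper | bfs < lower), logical(1))
  n_final <- if (any(decisive)) ns[which(decisive)[1]] else NA_integer_
  structure(list(
    checkpoints = data.frame(n = ns,
                             decision = ifelse(decisive, "stop", "continue")),
    bf_by_checkpoint = bf_by_checkpoint,
    upper = upper, lower = lower, n_final = n_final),
    class = "sequential_trace")
}

#' @export
print.sequential_trace <- function(x, ...) {
  print(x$checkpoints, row.names = FALSE)
  cat(if (is.na(x$n_final)) "never decisive\n"
      else sprintf("stopped at n = %d\n", x$n_final))
  invisible(x)
}
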