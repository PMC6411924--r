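# Independent oracles and small simulation helpers shared across test files.

# Simulate raw 2IFC trials from an observer at a fixed intensity difference.
simulate_observer_trials <- function(observer, n, delta = 1.2) {
  ti <- sample(1:2, n, replace = TRUE)
  out <- lapply(ti, function(t) sample_trial_outcome(observer, delta, t))
  data.frame(
    test_interval = ti,
    response_interval = vapply(out, `[[`, integer(1), "response_interval"),
    confidence = vapply(out, `[[`, integer(1), "confidence"),
    correct = vapply(out, `[[`, integer(1), "response_interval") == ti)
}

# Wrap a plain probability array as a type2_counts object (expected counts or
# multinomial draws from a known generating model).
as_type2_counts <- function(arr, K = dim(arr)[3], padding = "none") {
  structure(array(arr, dim = c(2, 2, K),
                  dimnames = list(stimulus = c("S1", "S2"),
                                  response = c("R1", "R2"),
                                  confidence = seq_len(K))),
            class = c("type2_counts", "array"), K = as.integer(K),
            padding = padding, n_dropped = 0L)
}

# Draw multinomial counts (n per stimulus class) from a joint probability
# table.
sample_counts_from_probs <- function(probs, n_per_class) {
  arr <- array(0, dim(probs))
  for (s in 1:2)
    arr[s, , ] <- stats::rmultinom(1, n_per_class, as.vector(probs[s, , ]))
  as_type2_counts(arr, dim(probs)[3])
}

# --- brute-force grid oracle for the K = 2 meta-d' fit ----------------------
# Written directly from the model definition with plain pnorm arithmetic;
# shares no code with the package's optimiser. Profile log-likelihood of the
# confidence counts conditional on (stimulus, response), maximised by
# iteratively refined exhaustive grid search over (meta_d, a, b) where a and b
# are the distances of the two type-2 criteria from the meta-level criterion.
grid_loglik_k2 <- function(counts, meta_d, a, b, cprime) {
  mc <- cprime * meta_d
  mu <- c(meta_d / 2, -meta_d / 2)
  ll <- 0
  for (s in 1:2) {
    # R1 side: conf 1 in (mc, mc + b), conf 2 above
    p_hi <- pnorm(mc + b - mu[s], lower.tail = FALSE)
    p_r1 <- pnorm(mc - mu[s], lower.tail = FALSE)
    p1 <- max(p_r1 - p_hi, 1e-300) / max(p_r1, 1e-300)
    p2 <- max(p_hi, 1e-300) / max(p_r1, 1e-300)
    ll <- ll + counts[s, 1, 1] * log(p1) + counts[s, 1, 2] * log(p2)
    # R2 side: conf 1 in (mc - a, mc), conf 2 below
    p_lo <- pnorm(mc - a - mu[s])
    p_r2 <- pnorm(mc - mu[s])
    q1 <- max(p_r2 - p_lo, 1e-300) / max(p_r2, 1e-300)
    q2 <- max(p_lo, 1e-300) / max(p_r2, 1e-300)
    ll <- ll + counts[s, 2, 1] * log(q1) + counts[s, 2, 2] * log(q2)
  }
  ll
}

grid_fit_meta_d_k2 <- function(counts, cprime, n_refine = 6) {
  lo <- c(-3, 0.01, 0.01); hi <- c(4, 3, 3)
  best <- NULL
  for (it in seq_len(n_refine)) {
    gr <- lapply(1:3, function(j) seq(lo[j], hi[j], length.out = 21))
    vals <- expand.grid(meta_d = gr[[1]], a = gr[[2]], b = gr[[3]])
    ll <- mapply(function(m, a, b) grid_loglik_k2(counts, m, a, b, cprime),
                 vals$meta_d, vals$a, vals$b)
    best <- cbind(vals[which.max(ll), ], ll = max(ll))
    w <- (hi - lo) / 20
    lo <- pmax(c(-3, 1e-4, 1e-4), unlist(best[1:3]) - w)
    hi <- unlist(best[1:3]) + w
  }
  best
}

# --- trapezoid quadrature oracles for the Bayes factors ---------------------
# Density of r given rho via Euler's integral representation of the
# hypergeometric term (different numerics from the package's series sum).
oracle_hyp2f1_half <- function(c_par, z, n_grid = 4000) {
  # Euler integral with t = u^2 to remove the endpoint singularity
  u <- seq(0, 1 - 1e-12, length.out = n_grid)
  f <- 2 * (1 - u^2)^(c_par - 1.5) * (1 - z * u^2)^(-0.5)
  exp(-lbeta(0.5, c_par - 0.5)) * sum((f[-1] + f[-n_grid]) / 2) * diff(u[1:2])
}

oracle_dens_r <- function(r, rho, n) {
  exp(log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5) +
        (n - 1) / 2 * log1p(-rho^2) + (n - 4) / 2 * log1p(-r^2) -
        (n - 1.5) * log1p(-rho * r)) *
    oracle_hyp2f1_half(n - 0.5, (rho * r + 1) / 2)
}

oracle_bf_correlation <- function(r, n, side = "two-sided", n_grid = 2001) {
  lims <- switch(side, "two-sided" = c(-1, 1), positive = c(0, 1),
                 negative = c(-1, 0))
  rho <- seq(lims[1] + 1e-7, lims[2] - 1e-7, length.out = n_grid)
  prior <- if (side == "two-sided") 0.5 else 1
  f <- vapply(rho, function(p) oracle_dens_r(r, p, n), numeric(1)) * prior
  area <- sum((f[-1] + f[-n_grid]) / 2) * diff(rho[1:2])
  area / oracle_dens_r(r, 0, n)
}

oracle_bf_ttest <- function(t, n, scale = sqrt(2) / 2, n_grid = 20001) {
  nu <- n - 1
  u <- seq(1e-7, 1 - 1e-7, length.out = n_grid)   # g = u / (1 - u)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  f <- (1 + n * g)^(-0.5) *
    (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
    scale / sqrt(2 * pi) * g^(-1.5) * exp(-scale^2 / (2 * g)) * jac
  num <- sum((f[-1] + f[-n_grid]) / 2) * diff(u[1:2])
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}
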