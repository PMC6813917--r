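# Independent oracles, written out from the definitions.

# Log partial likelihood of a one-covariate Cox model without ties,
# written directly from the product over event times.
cox_logpl <- function(beta, time, event, x) {
  s <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      s <- s + x[i] * beta - log(sum(exp(x[risk] * beta)))
    }
  }
  s
}

# Brute-force maximizer: coarse grid then golden-section refinement.
cox_brute_force <- function(time, event, x, lim = 10) {
  grid <- seq(-lim, lim, by = 0.05)
  ll <- vapply(grid, cox_logpl, numeric(1), time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  stats::optimize(function(b) -cox_logpl(b, time, event, x),
                  c(b0 - 0.1, b0 + 0.1), tol = 1e-9)$minimum
}

# Exhaustive-threshold BH oracle: a hypothesis is rejected iff some
# candidate threshold t (taken over the observed p-values) satisfies
# p_i <= t and m * t / #(p <= t) <= q.
bh_oracle <- function(p, q) {
  m <- length(p)
  reject <- logical(m)
  for (t in sort(unique(p))) {
    k <- sum(p <= t)
    if (m * t / k <= q) reject[p <= t] <- TRUE
  }
  reject
}

# Empirical survival (no censoring): fraction of observations exceeding t.
empirical_surv <- function(times, t) mean(times > t)

# Adjusted Rand index (contingency-table form).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  exp_idx <- sum_comb(rowSums(tab)) * sum_comb(colSums(tab)) / choose(n, 2)
  max_idx <- (sum_comb(rowSums(tab)) + sum_comb(colSums(tab))) / 2
  if (max_idx == exp_idx) return(1)
  (idx - exp_idx) / (max_idx - exp_idx)
}
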