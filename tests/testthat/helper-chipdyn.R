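# Shared fixtures and independent oracles, built in code.

# Exact method-of-steps solution of x'(t) = -x(t - 1), x == 1 for t <= 0.
# On interval k (t in [k-1, k]) the solution is a polynomial in u = t-(k-1);
# each interval integrates the previous one's polynomial analytically.
make_linear_dde_oracle <- function(n_intervals) {
  polys <- vector("list", n_intervals)
  prev <- 1          # x on [-1, 0]
  val <- 1           # x(0)
  for (k in seq_len(n_intervals)) {
    co <- -prev / seq_along(prev)          # antiderivative of -prev
    polys[[k]] <- c(val, co)
    val <- sum(polys[[k]])
    prev <- polys[[k]]
  }
  function(t) {
    vapply(t, function(ti) {
      if (ti <= 0) return(1)
      k <- min(ceiling(ti - 1e-12), n_intervals)
      u <- ti - (k - 1)
      sum(polys[[k]] * u^(seq_along(polys[[k]]) - 1))
    }, numeric(1))
  }
}

# Brute-force Welch statistic from the defining formulas.
welch_by_hand <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(statistic = t_stat, df = df, p.value = p)
}

# Repopulation summary at reduced cost for property sweeps (coarser step;
# the step-robustness test justifies the resolution).
quick_repop <- function(params, niche = niche_schedule(), step = 0.02, ...) {
  simulate_repopulation(params, niche = niche, step = step, ...)
}
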