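p_default <- hsc_params()

test_that("demand signals follow the exponential feedback law", {
  expect_equal(demand_signals(0, 0, p_default)$sigma_M, 1)
  expect_equal(demand_signals(90000, 0, p_default)$sigma_M, exp(-1))
  expect_equal(demand_signals(180000, 0, p_default)$sigma_M, exp(-2))
  expect_equal(demand_signals(0, 10000, p_default)$sigma_L, exp(-1))
  expect_error(demand_signals(-1, 0, p_default), ">= 0")
})

test_that("differentiation demand is the lineage-weighted combination", {
  expect_equal(differentiation_demand(list(sigma_M = 1, sigma_L = 1),
                                      p_default), 0.1)
  expect_equal(differentiation_demand(list(sigma_M = 1, sigma_L = 0),
                                      p_default), 0.06)
  expect_equal(differentiation_demand(list(sigma_M = exp(-1),
                                           sigma_L = exp(-1)), p_default),
               0.1 * exp(-1))
})

test_that("demand is bounded by gamma for any nonnegative state", {
  set.seed(11)
  # totals kept where exp(-total/K) stays above double-precision underflow;
  # far beyond, D rounds to exactly 0, its mathematical infimum
  for (i in 1:50) {
    sig <- demand_signals(runif(1, 0, 1e6), runif(1, 0, 1e6), p_default)
    D <- differentiation_demand(sig, p_default)
    expect_gt(D, 0)
    expect_lte(D, p_default$gamma)
  }
  huge <- demand_signals(1e9, 1e9, p_default)
  expect_equal(differentiation_demand(huge, p_default), 0)
})

test_that("effective death rates add Delta uniformly", {
  expect_equal(effective_death_rates(p_default, 0)[["delta_H"]], 0.001)
  expect_equal(effective_death_rates(p_default, 0.1)[["delta_H"]], 0.101)
  d <- effective_death_rates(p_default, 0.05)
  expect_equal(unname(d[c("delta_M", "delta_L")]), c(0.30, 0.15))
  expect_error(effective_death_rates(p_default, -0.01), ">= 0")
})

test_that("right-hand side matches hand-computed values", {
  s <- c(100, 0, 0, 0, 0, 0)
  f <- system_rhs(s, s, p_default, delta = 0)
  # 0.1*100*(1 - 100/10000) - 0.1*100 - 0.001*100
  expect_equal(f[["H1"]], -0.2)
  expect_equal(f[["H2"]], 0)
  expect_equal(f[["M1"]], 60000)
  expect_equal(f[["L1"]], 40000)
  # HSC extinction is absorbing
  f0 <- system_rhs(c(0, 0, 5e4, 5e4, 1e4, 1e4), c(0, 0, 0, 0, 0, 0),
                   p_default, 0)
  expect_equal(f0[["H1"]], 0)
  expect_equal(f0[["H2"]], 0)
})

test_that("derivative field has clone-swap symmetry", {
  set.seed(7)
  for (i in 1:20) {
    p <- hsc_params(rho = runif(1, 0.3, 3), h1 = runif(1, 0, 3),
                    h2 = runif(1, 0, 3))
    # swapped parameterization: clone 2's growth becomes clone 1's
    p_swap <- hsc_params(r1 = p$r2, rho = p$r1 / p$r2, h1 = p$h2,
                         h2 = p$h1)
    y <- runif(6, 0, 2e5)
    yd <- runif(6, 0, 2e5)
    swap <- c(2, 1, 4, 3, 6, 5)
    delta <- runif(1, 0, 0.1)
    f <- system_rhs(y, yd, p, delta)
    f_swap <- system_rhs(y[swap], yd[swap], p_swap, delta)
    expect_equal(unname(f_swap), unname(f[swap]), tolerance = 1e-12)
  }
})

test_that("each compartment's flow cannot cross zero", {
  set.seed(13)
  for (i in 1:20) {
    p <- hsc_params(rho = runif(1, 0.3, 3), h1 = runif(1, 0, 3),
                    h2 = runif(1, 0, 3))
    y <- runif(6, 0, 2e5)
    yd <- runif(6, 0, 2e5)
    for (j in 1:6) {
      yj <- y; yj[j] <- 0
      f <- system_rhs(yj, yd, p, runif(1, 0, 0.1))
      expect_gte(f[[j]], 0)
    }
  }
})

test_that("symmetric clones give identical derivatives, summing to one logistic clone", {
  y <- c(3000, 3000, 4e6, 4e6, 8e6, 8e6)
  yd <- c(2500, 2500, 3e6, 3e6, 7e6, 7e6)
  f <- system_rhs(y, yd, p_default, 0)
  expect_equal(f[["H1"]], f[["H2"]])
  expect_equal(f[["M1"]], f[["M2"]])
  expect_equal(f[["L1"]], f[["L2"]])
  # healthy degeneracy: with h1 = h2 = 1, rho = 1 the summed HSC pool obeys
  # a single logistic-with-demand equation
  H <- y[1] + y[2]
  sig <- demand_signals(y[3] + y[4], y[5] + y[6], p_default)
  D <- differentiation_demand(sig, p_default)
  dH_single <- p_default$r1 * H * (1 - H / p_default$K_H) - D * H -
    p_default$delta_H0 * H
  expect_equal(f[["H1"]] + f[["H2"]], dH_single, tolerance = 1e-12)
})

test_that("compiled and R right-hand sides agree", {
  set.seed(19)
  for (i in 1:20) {
    p <- hsc_params(rho = runif(1, 0.3, 3), h1 = runif(1, 0, 3),
                    h2 = runif(1, 0, 3))
    y <- runif(6, 0, 2e5)
    yd <- runif(6, 0, 2e5)
    delta <- runif(1, 0, 0.1)
    f_r <- system_rhs(y, yd, p, delta)
    f_cpp <- chipdyn:::.hsc_rhs_cpp(y, yd, chipdyn:::.pack_params(p), delta)
    expect_equal(unname(f_r), f_cpp, tolerance = 1e-13)
  }
})
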