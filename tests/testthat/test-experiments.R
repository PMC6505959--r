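p_default <- hsc_params()

test_that("healthy repopulation is clone-symmetric and reaches the logistic level", {
  rec <- simulate_repopulation(p_default)
  traj <- rec$trajectory
  # exact symmetry: identical equations and identical initial data
  expect_identical(traj$state[, "H1"], traj$state[, "H2"])
  expect_false(rec$summary$extinct)
  expect_true(rec$summary$settled)
  expect_equal(rec$summary$ratio, 1)
  # zero-demand fixed point K_H (1 - delta_H0/r1) = 9900 (demand is
  # negligible because daughters sit far above K_M, K_L)
  expect_equal(rec$summary$H_total, 9900, tolerance = 0.01)
  expect_lt(rec$summary$D, 0.01 * p_default$gamma)
})

test_that("daughter compartments are slaved to the HSC steady state", {
  rec <- simulate_repopulation(p_default)
  s <- rec$summary
  fp <- daughter_fixed_point(s$final[["H1"]], s$final[["H2"]], p_default, 0)
  expect_equal(s$final[["M1"]], fp$M1, tolerance = 0.01)
  expect_equal(s$final[["L1"]], fp$L1, tolerance = 0.01)
})

test_that("supercritical niche damage drives the stem cell pool extinct", {
  rec <- simulate_repopulation(p_default, niche_schedule(0.12))
  expect_lt(rec$summary$H_total, 10)
  expect_true(rec$summary$extinct)
})

test_that("all-zero seeding is absorbing for HSCs", {
  rec <- simulate_repopulation(p_default, seed_cells = 0, t_end = 30,
                               step = 0.1)
  expect_equal(max(rec$trajectory$state[, c("H1", "H2")]), 0)
})

test_that("competition/growth sweep reproduces the qualitative regimes", {
  sw <- competition_growth_sweep(h_values = c(0.5, 1, 2),
                                 rho_values = c(0.5, 1, 2),
                                 params = p_default, step = 0.02)
  expect_s3_class(sw, "hsc_sweep")
  expect_equal(nrow(sw), 9L)
  ref <- sw[sw$h == 1 & sw$rho == 1, ]
  # healthy reference point: exact clone symmetry
  expect_equal(ref$ratio, 1)
  # the faster clone always ends at least as large as the slower one
  fast2 <- sw$rho > 1
  expect_true(all(sw$H2[fast2] >= sw$H1[fast2]))
  fast1 <- sw$rho < 1
  expect_true(all(sw$H1[fast1] >= sw$H2[fast1]))
  # relaxed competition exceeds the joint-carrying-capacity total
  expect_gt(sw$H_total[sw$h == 0.5 & sw$rho == 1], ref$H_total)
  # strong competition with a growth disparity: competitive exclusion of
  # the slower clone at conserved total
  excl <- sw[sw$h == 2 & sw$rho == 2, ]
  expect_lt(excl$H1, 0.01 * excl$H_total)
  expect_equal(excl$H_total, ref$H_total, tolerance = 0.01)
})

test_that("competition magnifies a fixed growth-rate imbalance", {
  hs <- c(0.5, 1, 1.5, 2)
  sw <- competition_growth_sweep(h_values = hs, rho_values = 1.5,
                                 params = p_default, step = 0.02)
  lr <- abs(log(sw$ratio[order(sw$h)]))
  expect_true(all(diff(lr) >= -1e-8))
})

test_that("niche damage sweep: totals fall with damage and with competition", {
  sw <- niche_damage_sweep(delta_values = c(0, 0.05, 0.15),
                           h_values = c(1, 2, 3),
                           params = p_default, step = 0.02)
  expect_equal(sw$H_total[sw$delta == 0 & sw$h == 1], 9900,
               tolerance = 0.01)
  # H_total non-increasing in Delta at fixed h
  for (h in unique(sw$h)) {
    col <- sw[sw$h == h, ]
    expect_true(all(diff(col$H_total[order(col$delta)]) <= 1e-6))
  }
  # and non-increasing in h at fixed damage
  at05 <- sw[sw$delta == 0.05, ]
  expect_true(all(diff(at05$H_total[order(at05$h)]) <= 1e-6))
  # beyond the threshold every competition intensity goes extinct
  expect_true(all(sw$extinct[sw$delta == 0.15]))
})

test_that("extinction threshold sits near 0.10/day and behaves monotonically", {
  th <- find_extinction_threshold(p_default, step = 0.02)
  expect_lt(abs(th$threshold - 0.10), 0.01)
  # definition check around the refined threshold
  below <- simulate_repopulation(p_default,
                                 niche_schedule(th$threshold - 0.02),
                                 step = 0.02)$summary
  above <- simulate_repopulation(p_default,
                                 niche_schedule(th$threshold + 0.02),
                                 step = 0.02)$summary
  expect_false(below$extinct)
  expect_true(above$extinct)
  # more growth headroom moves the threshold up
  th2 <- find_extinction_threshold(update_params(p_default, r1 = 0.2),
                                   delta_grid = seq(0, 0.3, by = 0.01),
                                   step = 0.02)
  expect_gt(th2$threshold, th$threshold)
  # no extinction on a low grid is reported, not fabricated
  none <- find_extinction_threshold(p_default,
                                    delta_grid = c(0, 0.01, 0.02),
                                    step = 0.05)
  expect_true(is.na(none$threshold))
  expect_match(none$message, "no threshold")
})

test_that("growth-factor support helps but does not restore the healthy state", {
  gf <- growth_factor_intervention(p_default, delta = 0.05, step = 0.02)
  expect_gte(gf$treated$H_total, gf$untreated$H_total)
  expect_gte(gf$treated$M_total, gf$untreated$M_total)
  expect_gte(gf$treated$L_total, gf$untreated$L_total)
  expect_lt(gf$treated$H_total, gf$healthy$H_total)
  # Delta = 0: the three runs coincide exactly
  gf0 <- growth_factor_intervention(p_default, delta = 0, t_end = 40,
                                    step = 0.05)
  expect_equal(gf0$treated$final, gf0$untreated$final)
  expect_equal(gf0$treated$final, gf0$healthy$final)
})

test_that("homeostatic demand reflects daughter shortfall", {
  rec <- simulate_repopulation(p_default, step = 0.02)
  D_healthy <- demand_at_homeostasis(rec$trajectory)
  expect_lt(D_healthy, 0.01 * p_default$gamma)
  # lower-production regime (rho = 1, h > 1) has higher demand
  rec_h <- simulate_repopulation(update_params(p_default, h1 = 3, h2 = 3),
                                 step = 0.02)
  expect_gt(demand_at_homeostasis(rec_h$trajectory), D_healthy)
  # empty daughter compartments give the maximal demand gamma
  sig <- demand_signals(0, 0, p_default)
  expect_equal(differentiation_demand(sig, p_default), p_default$gamma)
})
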