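test_that("pure exponential decay matches the closed form", {
  # turn off growth, demand and daughter influx; only HSC death d = 0.1
  # remains (baseline 0.001 + Delta 0.099)
  p <- hsc_params(r1 = 1e-12, gamma = 1e-12, alpha_M = 1e-12,
                  alpha_L = 1e-12, delta_H0 = 0.001)
  traj <- dde_integrate(p, history = 100, niche = niche_schedule(0.099),
                        t_end = 10, step = 0.01)
  H10 <- state_at(traj, 10)[["H1"]]
  expect_equal(H10, 100 * exp(-1), tolerance = 1e-9)
  # interpolated off-grid values also track the closed form
  for (t in c(1.234, 5.5551, 9.87654)) {
    expect_equal(state_at(traj, t)[["H1"]], 100 * exp(-0.1 * t),
                 tolerance = 1e-9)
  }
})

test_that("constant delayed influx grows daughters linearly, independent of tau", {
  # all HSC dynamics off and delta_M ~ 0: M1' = alpha_M * phi * H1(t - tau)
  # with H1 pinned at its 100-cell history, so M1(t) = 100 + c * t
  for (tau in c(5, 14)) {
    p <- hsc_params(r1 = 1e-12, gamma = 1e-12, delta_H0 = 1e-12,
                    delta_M0 = 1e-12, delta_L0 = 1e-12, alpha_M = 10,
                    alpha_L = 10, tau = tau)
    traj <- dde_integrate(p, history = 100, t_end = 20, step = 0.1)
    c_in <- p$alpha_M * p$phi * 100
    expect_equal(state_at(traj, 20)[["M1"]], 100 + c_in * 20,
                 tolerance = 1e-8)
  }
})

test_that("generic RK4-DDE reproduces the method-of-steps worked example", {
  sol <- rk4_dde(function(t, x, xl) -xl, history = 1, tau = 1,
                 t_end = 2, step = 0.05)
  x_at <- function(t) sol$state[round(t / 0.05) + 1]
  expect_equal(x_at(1), 0, tolerance = 1e-10)
  expect_equal(x_at(2), -0.5, tolerance = 1e-10)
  # exact polynomial oracle over a longer span
  oracle <- make_linear_dde_oracle(8)
  expect_equal(oracle(1), 0)
  expect_equal(oracle(2), -0.5)
  sol6 <- rk4_dde(function(t, x, xl) -xl, history = 1, tau = 1,
                  t_end = 6, step = 0.05)
  expect_equal(sol6$state[length(sol6$state)], oracle(6), tolerance = 1e-6)
})

test_that("the scheme converges at fourth order on the linear DDE", {
  oracle <- make_linear_dde_oracle(8)
  x6 <- oracle(6)
  err <- vapply(c(0.2, 0.1, 0.05), function(h) {
    sol <- rk4_dde(function(t, x, xl) -xl, history = 1, tau = 1,
                   t_end = 6, step = h)
    abs(sol$state[length(sol$state)] - x6)
  }, numeric(1))
  orders <- log2(err[-length(err)] / err[-1])
  expect_true(all(orders >= 3.5))
})

test_that("compiled solver agrees with the generic R route and with deSolve", {
  p <- hsc_params(rho = 1.5, h1 = 1.2, h2 = 0.8)
  delta <- 0.02
  traj <- dde_integrate(p, history = 100, niche = niche_schedule(delta),
                        t_end = 30, step = 0.1)
  rhs_r <- function(t, y, ylag) system_rhs(y, ylag, p, delta)
  ref <- rk4_dde(rhs_r, history = rep(100, 6), tau = p$tau, t_end = 30,
                 step = 0.1)
  expect_equal(unname(traj$state[nrow(traj$state), ]),
               unname(ref$state[nrow(ref$state), ]), tolerance = 1e-12)

  # independent adaptive-step route (deSolve lsoda with lagged state)
  dede_rhs <- function(t, y, parms) {
    ylag <- if (t <= p$tau) rep(100, 6) else deSolve::lagvalue(t - p$tau)
    list(unname(system_rhs(y, ylag, p, delta)))
  }
  out <- deSolve::dede(y = rep(100, 6), times = seq(0, 30, by = 1),
                       func = dede_rhs, parms = NULL,
                       atol = 1e-8, rtol = 1e-8)
  expect_equal(unname(traj$state[nrow(traj$state), ]),
               unname(out[nrow(out), -1]), tolerance = 1e-4)
})

test_that("halving the default step leaves final states unchanged to 1e-6", {
  p <- hsc_params(rho = 1.3, h1 = 1.5, h2 = 1.5)
  f1 <- dde_integrate(p, t_end = 280, step = 0.01)$state
  f2 <- dde_integrate(p, t_end = 280, step = 0.005)$state
  a <- f1[nrow(f1), ]
  b <- f2[nrow(f2), ]
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("trajectories are deterministic, nonnegative, on a uniform grid", {
  p <- hsc_params(rho = 2, h1 = 2, h2 = 2)
  t1 <- dde_integrate(p, t_end = 60, step = 0.02)
  t2 <- dde_integrate(p, t_end = 60, step = 0.02)
  expect_identical(t1$state, t2$state)
  expect_true(all(t1$state >= 0))
  expect_equal(diff(t1$time), rep(0.02, length(t1$time) - 1))
})

test_that("state_at honors history, grid points and range limits", {
  traj <- dde_integrate(hsc_params(), t_end = 20, step = 0.1)
  expect_equal(unname(state_at(traj, -5)), rep(100, 6))
  expect_equal(unname(state_at(traj, 0)), rep(100, 6))
  i <- 87
  expect_equal(state_at(traj, traj$time[i]), traj$state[i, ])
  expect_error(state_at(traj, 21), "range")
  expect_error(state_at(traj, -15), "range")
})

test_that("solver rejects invalid configurations", {
  p <- hsc_params()
  expect_error(dde_integrate(p, step = 15), "tau")
  expect_error(dde_integrate(p, t_end = -1), "positive")
  expect_error(dde_integrate(p, t_end = 1, step = 0.3), "multiple")
  expect_error(dde_integrate(p, history = c(-1, rep(100, 5)), t_end = 1,
                             step = 0.1), ">= 0")
  expect_error(
    dde_integrate(p, niche = niche_schedule(0.1, treatment_time = 15.005),
                  t_end = 30, step = 0.01 * 3), "boundary")
  expect_error(
    dde_integrate(p, niche = niche_schedule(0.1, treatment_time = 40),
                  t_end = 30, step = 0.1), "span")
})

test_that("trajectory CSV round-trips through the writer", {
  traj <- dde_integrate(hsc_params(), t_end = 5, step = 0.5)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  df <- read.csv(f)
  expect_equal(names(df), c("t", "H1", "H2", "M1", "M2", "L1", "L2"))
  expect_equal(df$H1, unname(traj$state[, "H1"]))
  unlink(f)
})
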