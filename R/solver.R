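#' Integrate the clonal hematopoiesis DDE system
#'
#' Fixed-step classical Runge-Kutta (RK4) integration of the six-compartment
#' delay system with constant pre-simulation history and cubic Hermite dense
#' output for the delayed-state lookup. When the niche schedule carries a
#' treatment time, the Heaviside drop of Delta is required to fall exactly on
#' a step boundary so that Delta is constant within every step.
#'
#' @param params an [hsc_params()] object.
#' @param history constant state applied for all `t <= 0`, either a single
#'   number (every compartment) or a length-6 vector
#'   `(H1, H2, M1, M2, L1, L2)`; also the initial state at `t = 0`.
#' @param niche a [niche_schedule()].
#' @param t_end simulation horizon (days), a positive multiple of `step`.
#' @param step integration step (days); must satisfy `0 < step <= tau`.
#' @return An object of class `hsc_trajectory`: uniform time grid, state
#'   matrix (columns H1, H2, M1, M2, L1, L2), stored derivatives for dense
#'   interpolation, the step, parameters, niche schedule and history used.
#' @examples
#' traj <- dde_integrate(hsc_params(), t_end = 30, step = 0.05)
#' state_at(traj, 30)
#' @seealso [state_at()], [simulate_repopulation()]
#' @export
dde_integrate <- function(params, history = 100, niche = niche_schedule(),
                          t_end = 280, step = 0.01) {
  stopifnot(inherits(params, "hsc_params"), inherits(niche, "niche_schedule"))
  if (!is.numeric(t_end) || length(t_end) != 1L || t_end <= 0)
    stop("t_end must be a single positive number", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a single positive number", call. = FALSE)
  if (step > params$tau)
    stop("step must not exceed the delay tau (delayed lookup would precede ",
         "the resolved solution)", call. = FALSE)
  n <- round(t_end / step)
  if (n < 1 || abs(n * step - t_end) > 1e-8 * max(1, t_end))
    stop("t_end must be a positive integer multiple of step", call. = FALSE)
  if (length(history) == 1L) history <- rep(history, 6L)
  history <- .check_state(history, "history")
  if (any(history < 0))
    stop("history states must be >= 0", call. = FALSE)
  tt <- niche$treatment_time
  if (!is.null(tt)) {
    if (tt > t_end)
      stop("treatment_time must lie within the simulation span", call. = FALSE)
    if (abs(round(tt / step) * step - tt) > 1e-8)
      stop("treatment_time must fall on a step boundary (a multiple of step)",
           call. = FALSE)
  }
  res <- .hsc_integrate_cpp(.pack_params(params), unname(history),
                            unname(history), niche$delta,
                            if (is.null(tt)) NA_real_ else tt, t_end, step)
  if (res$clipped > 0)
    warning(sprintf("clipped %d negative state value(s) to 0 (numerical undershoot)",
                    as.integer(res$clipped)))
  state <- res$state
  colnames(state) <- .state_names
  deriv <- res$deriv
  colnames(deriv) <- .state_names
  structure(list(time = res$time, state = state, deriv = deriv,
                 step = step, params = params, niche = niche,
                 history = history, clipped = as.integer(res$clipped)),
            class = "hsc_trajectory")
}

#' Interpolated state lookup on a trajectory
#'
#' Returns the system state at an arbitrary time: the constant history for
#' `t <= 0`, the stored value exactly at grid points, and cubic Hermite
#' interpolation (values and derivatives at the bracketing nodes) between
#' them.
#'
#' @param traj an `hsc_trajectory` from [dde_integrate()].
#' @param t time (days), `-tau <= t <= t_end`.
#' @return Named state vector `(H1, H2, M1, M2, L1, L2)` (cells).
#' @export
state_at <- function(traj, t) {
  stopifnot(inherits(traj, "hsc_trajectory"), is.numeric(t), length(t) == 1L)
  t_end <- traj$time[length(traj$time)]
  if (t < -traj$params$tau - 1e-9 || t > t_end + 1e-9)
    stop("t outside the trajectory range [-tau, t_end]", call. = FALSE)
  if (t <= 0) return(traj$history)
  h <- traj$step
  u <- t / h
  k <- floor(u + 1e-9)
  th <- u - k
  n <- length(traj$time) - 1L
  if (k >= n) { k <- n; th <- 0 }
  if (th < 1e-12) {
    out <- traj$state[k + 1L, ]
    return(out)
  }
  h00 <- 2 * th^3 - 3 * th^2 + 1
  h10 <- th^3 - 2 * th^2 + th
  h01 <- -2 * th^3 + 3 * th^2
  h11 <- th^3 - th^2
  out <- h00 * traj$state[k + 1L, ] + h10 * h * traj$deriv[k + 1L, ] +
    h01 * traj$state[k + 2L, ] + h11 * h * traj$deriv[k + 2L, ]
  out
}

#' @export
print.hsc_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat(sprintf("Hematopoiesis DDE trajectory: %d points over [0, %g] d (step %g d)\n",
              n, x$time[n], x$step))
  fin <- x$state[n, ]
  cat(sprintf("  Final HSC total %.4g cells (H1 = %.4g, H2 = %.4g)\n",
              fin[["H1"]] + fin[["H2"]], fin[["H1"]], fin[["H2"]]))
  cat(sprintf("  Final myeloid %.4g, lymphoid %.4g cells\n",
              fin[["M1"]] + fin[["M2"]], fin[["L1"]] + fin[["L2"]]))
  print(x$niche)
  invisible(x)
}

#' @export
summary.hsc_trajectory <- function(object, ...) {
  n <- length(object$time)
  fin <- object$state[n, ]
  sig <- demand_signals(fin[["M1"]] + fin[["M2"]], fin[["L1"]] + fin[["L2"]],
                        object$params)
  out <- list(t_end = object$time[n], step = object$step, final = fin,
              H_total = fin[["H1"]] + fin[["H2"]],
              M_total = fin[["M1"]] + fin[["M2"]],
              L_total = fin[["L1"]] + fin[["L2"]],
              D = differentiation_demand(sig, object$params),
              clipped = object$clipped)
  class(out) <- "summary.hsc_trajectory"
  out
}

#' @export
print.summary.hsc_trajectory <- function(x, ...) {
  cat(sprintf("State at t = %g d:\n", x$t_end))
  print(round(x$final, 4))
  cat(sprintf("Totals: HSC %.4g, myeloid %.4g, lymphoid %.4g cells; demand D = %.3g /d\n",
              x$H_total, x$M_total, x$L_total, x$D))
  invisible(x)
}

#' @export
as.data.frame.hsc_trajectory <- function(x, ...) {
  data.frame(t = x$time, x$state, check.names = FALSE)
}

#' @export
plot.hsc_trajectory <- function(x, log = "y", ...) {
  st <- pmax(x$state, if (grepl("y", log)) 1e-2 else 0)
  graphics::matplot(x$time, st, type = "l", lty = rep(1:3, each = 2),
                    col = rep(c("black", "firebrick"), 3), log = log,
                    xlab = "time (days)", ylab = "cells", ...)
  graphics::legend("bottomright", legend = .state_names, bty = "n",
                   lty = rep(1:3, each = 2),
                   col = rep(c("black", "firebrick"), 3))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Tidy delimited output with columns `t, H1, H2, M1, M2, L1, L2` at full
#' double precision; time in days, populations in cells.
#'
#' @param traj an `hsc_trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hsc_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Generic fixed-step RK4 integrator for a constant-history DDE
#'
#' Method-of-steps RK4 for `x'(t) = f(t, x(t), x(t - tau))` with a constant
#' history and cubic Hermite dense output for the delayed lookup, for
#' arbitrary state dimension. This is the same scheme the compiled
#' hematopoiesis integrator uses; it exists as an independent, generic route
#' for verification problems (scalar linear DDEs with known method-of-steps
#' solutions) and cross-checks.
#'
#' @param rhs function `f(t, x, xlag)` returning the derivative vector.
#' @param history constant state vector for `t <= 0`.
#' @param tau delay (same time units as `t`); `step <= tau` required.
#' @param t_end horizon, a positive multiple of `step`.
#' @param step step size.
#' @return A list with `time` (grid) and `state` (matrix, one row per time).
#' @examples
#' # x'(t) = -x(t - 1), x == 1 for t <= 0: x(1) = 0, x(2) = -0.5
#' sol <- rk4_dde(function(t, x, xl) -xl, 1, tau = 1, t_end = 2, step = 0.1)
#' sol$state[c(11, 21)]
#' @export
rk4_dde <- function(rhs, history, tau, t_end, step) {
  stopifnot(is.function(rhs), tau > 0, step > 0, step <= tau + 1e-12)
  n <- round(t_end / step)
  stopifnot(n >= 1, abs(n * step - t_end) < 1e-8 * max(1, t_end))
  d <- length(history)
  Y <- matrix(NA_real_, n + 1L, d)
  F <- matrix(NA_real_, n + 1L, d)
  Y[1L, ] <- history
  lookup <- function(td, filled) {
    if (td <= 0) return(history)
    u <- td / step
    k <- floor(u + 1e-9)
    if (k > filled - 1L) k <- filled - 1L
    th <- u - k
    if (th < 1e-12) return(Y[k + 1L, ])
    h00 <- 2 * th^3 - 3 * th^2 + 1
    h10 <- th^3 - 2 * th^2 + th
    h01 <- -2 * th^3 + 3 * th^2
    h11 <- th^3 - th^2
    h00 * Y[k + 1L, ] + h10 * step * F[k + 1L, ] +
      h01 * Y[k + 2L, ] + h11 * step * F[k + 2L, ]
  }
  F[1L, ] <- rhs(0, Y[1L, ], lookup(-tau, 0L))
  for (i in seq_len(n)) {
    t0 <- (i - 1L) * step
    y <- Y[i, ]
    xl1 <- lookup(t0 - tau, i - 1L)
    k1 <- rhs(t0, y, xl1)
    xl2 <- lookup(t0 + step / 2 - tau, i - 1L)
    k2 <- rhs(t0 + step / 2, y + step / 2 * k1, xl2)
    k3 <- rhs(t0 + step / 2, y + step / 2 * k2, xl2)
    xl4 <- lookup(t0 + step - tau, i - 1L)
    k4 <- rhs(t0 + step, y + step * k3, xl4)
    Y[i + 1L, ] <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    F[i + 1L, ] <- rhs(i * step, Y[i + 1L, ], lookup(i * step - tau, i))
  }
  list(time = (0:n) * step, state = drop(Y))
}
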