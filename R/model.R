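#' Demand feedback signals
#'
#' Exponential negative-feedback signals driving HSC differentiation: each
#' signal is 1 when its mature compartment is empty and decays toward 0 as
#' the compartment total approaches (and exceeds) its carrying capacity,
#' `sigma_M = exp(-M_total / K_M)` and `sigma_L = exp(-L_total / K_L)`.
#'
#' @param M_total,L_total total myeloid and lymphoid cells (both clones),
#'   `>= 0`.
#' @param params an [hsc_params()] object.
#' @return A list with components `sigma_M` and `sigma_L`, each in (0, 1].
#' @examples
#' demand_signals(0, 0, hsc_params())          # both 1
#' demand_signals(90000, 0, hsc_params())$sigma_M  # exp(-1)
#' @export
demand_signals <- function(M_total, L_total, params) {
  stopifnot(inherits(params, "hsc_params"))
  if (any(M_total < 0) || any(L_total < 0))
    stop("compartment totals must be >= 0", call. = FALSE)
  list(sigma_M = exp(-M_total / params$K_M),
       sigma_L = exp(-L_total / params$K_L))
}

#' Differentiation demand
#'
#' The per-capita HSC differentiation loss rate,
#' `D = gamma * (phi * sigma_M + (1 - phi) * sigma_L)` (day^-1): a
#' lineage-weighted combination of the two demand signals, bounded above by
#' `gamma`.
#'
#' @param signals a list with `sigma_M` and `sigma_L` as returned by
#'   [demand_signals()].
#' @param params an [hsc_params()] object.
#' @return Demand rate D (day^-1), in (0, gamma\].
#' @export
differentiation_demand <- function(signals, params) {
  stopifnot(inherits(params, "hsc_params"))
  params$gamma * (params$phi * signals$sigma_M +
                    (1 - params$phi) * signals$sigma_L)
}

#' Effective death rates under niche degradation
#'
#' Adds the degradation increment Delta uniformly to the three baseline
#' death rates.
#'
#' @param params an [hsc_params()] object.
#' @param delta degradation increment (day^-1), `>= 0`.
#' @return Named vector `c(delta_H, delta_M, delta_L)` (day^-1).
#' @export
effective_death_rates <- function(params, delta) {
  stopifnot(inherits(params, "hsc_params"))
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0)
    stop("delta must be a single finite number >= 0", call. = FALSE)
  c(delta_H = params$delta_H0 + delta,
    delta_M = params$delta_M0 + delta,
    delta_L = params$delta_L0 + delta)
}

.state_names <- c("H1", "H2", "M1", "M2", "L1", "L2")

.check_state <- function(x, what = "state") {
  if (!is.numeric(x) || length(x) != 6L)
    stop(what, " must be a numeric vector of length 6 (H1, H2, M1, M2, L1, L2)",
         call. = FALSE)
  x <- as.numeric(x)
  names(x) <- .state_names
  x
}

#' Right-hand side of the six-compartment DDE system
#'
#' Time derivatives of the two HSC clones and their myeloid and lymphoid
#' daughter compartments. HSC renewal is logistic with cross-clone
#' Lotka-Volterra competition; HSC loss combines demand-driven
#' differentiation (signals evaluated from the *current* daughter totals)
#' and death; daughter influx is the amplified, lineage-split HSC population
#' at the delayed time `t - tau`, supplied as `delayed`.
#'
#' @param current state vector `(H1, H2, M1, M2, L1, L2)` at time t (cells).
#' @param delayed state vector at time `t - tau` (cells); only its HSC
#'   entries enter the derivatives.
#' @param params an [hsc_params()] object.
#' @param delta niche degradation increment at time t (day^-1).
#' @return Named numeric vector of the six time derivatives (cells/day).
#' @examples
#' p <- hsc_params()
#' s <- c(100, 0, 0, 0, 0, 0)
#' system_rhs(s, s, p, delta = 0)  # dH1/dt = -0.2, dM1/dt = 60000
#' @export
system_rhs <- function(current, delayed, params, delta = 0) {
  stopifnot(inherits(params, "hsc_params"))
  y <- .check_state(current, "current")
  yd <- .check_state(delayed, "delayed")
  sig <- demand_signals(y[["M1"]] + y[["M2"]], y[["L1"]] + y[["L2"]], params)
  D <- differentiation_demand(sig, params)
  d <- effective_death_rates(params, delta)
  with(params, {
    out <- c(
      H1 = r1 * y[["H1"]] * (1 - (y[["H1"]] + h2 * y[["H2"]]) / K_H) -
        D * y[["H1"]] - d[["delta_H"]] * y[["H1"]],
      H2 = r2 * y[["H2"]] * (1 - (y[["H2"]] + h1 * y[["H1"]]) / K_H) -
        D * y[["H2"]] - d[["delta_H"]] * y[["H2"]],
      M1 = alpha_M * phi * yd[["H1"]] - d[["delta_M"]] * y[["M1"]],
      M2 = alpha_M * phi * yd[["H2"]] - d[["delta_M"]] * y[["M2"]],
      L1 = alpha_L * (1 - phi) * yd[["H1"]] - d[["delta_L"]] * y[["L1"]],
      L2 = alpha_L * (1 - phi) * yd[["H2"]] - d[["delta_L"]] * y[["L2"]]
    )
    out
  })
}
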