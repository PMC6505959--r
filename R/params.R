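#' Model parameters for the two-clone hematopoiesis model
#'
#' Constructs and validates the full parameter set of the clonal competition
#' model: logistic HSC renewal with Lotka-Volterra competition between a
#' healthy clone (1) and a mutant clone (2), demand-feedback differentiation
#' into delayed myeloid and lymphoid compartments, and baseline death rates
#' that a niche-degradation increment can augment (see
#' [niche_schedule()]).
#'
#' Defaults are the healthy-clone reference parameterization. The mutant
#' growth rate is never set directly: `r2 = rho * r1` is derived, so the
#' relative mutant growth rate `rho` is the single growth-disparity knob.
#'
#' @param r1 maximum per-capita growth rate of healthy HSCs (day^-1).
#' @param rho relative mutant growth rate, dimensionless; `r2 = rho * r1`.
#' @param h1 competition coefficient clone 1 exerts on clone 2 (dimensionless).
#' @param h2 competition coefficient clone 2 exerts on clone 1 (dimensionless).
#' @param K_H HSC carrying capacity (cells).
#' @param gamma differentiation-demand scaling (day^-1); the per-capita
#'   differentiation loss is at most `gamma`.
#' @param phi myeloid fraction of differentiation, in \[0, 1\].
#' @param delta_H0,delta_M0,delta_L0 baseline death rates of HSCs, myeloid
#'   and lymphoid cells (day^-1).
#' @param alpha_M,alpha_L amplification factors from HSC differentiation flux
#'   to mature daughter production (dimensionless).
#' @param tau maturation delay between HSC commitment and appearance of
#'   mature daughters (days).
#' @param K_M,K_L myeloid and lymphoid carrying capacities (cells), the
#'   scales of the demand feedback signals.
#'
#' @return An object of class `hsc_params`: a named list of the validated
#'   parameters plus the derived `r2`.
#' @examples
#' p <- hsc_params(rho = 2, h1 = 1.5, h2 = 1.5)
#' p$r2  # 0.2
#' @export
hsc_params <- function(r1 = 0.1, rho = 1, h1 = 1, h2 = 1, K_H = 10000,
                       gamma = 0.1, phi = 0.6,
                       delta_H0 = 0.001, delta_M0 = 0.25, delta_L0 = 0.1,
                       alpha_M = 1000, alpha_L = 1000, tau = 14,
                       K_M = 90000, K_L = 10000) {
  p <- list(r1 = r1, rho = rho, h1 = h1, h2 = h2, K_H = K_H, gamma = gamma,
            phi = phi, delta_H0 = delta_H0, delta_M0 = delta_M0,
            delta_L0 = delta_L0, alpha_M = alpha_M, alpha_L = alpha_L,
            tau = tau, K_M = K_M, K_L = K_L)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  strict_pos <- c("r1", "rho", "K_H", "gamma", "delta_H0", "delta_M0",
                  "delta_L0", "alpha_M", "alpha_L", "tau", "K_M", "K_L")
  for (nm in strict_pos)
    if (p[[nm]] <= 0)
      stop("parameter '", nm, "' must be strictly positive", call. = FALSE)
  if (h1 < 0 || h2 < 0)
    stop("competition coefficients h1, h2 must be >= 0", call. = FALSE)
  if (phi < 0 || phi > 1)
    stop("myeloid fraction phi must lie in [0, 1]", call. = FALSE)
  p$r2 <- rho * r1
  class(p) <- "hsc_params"
  p
}

#' @export
print.hsc_params <- function(x, ...) {
  cat("Two-clone hematopoiesis model parameters\n")
  cat(sprintf("  HSC growth:     r1 = %g, rho = %g (r2 = %g) day^-1; K_H = %g cells\n",
              x$r1, x$rho, x$r2, x$K_H))
  cat(sprintf("  Competition:    h1 = %g, h2 = %g\n", x$h1, x$h2))
  cat(sprintf("  Differentiation: gamma = %g day^-1, phi = %g, tau = %g d\n",
              x$gamma, x$phi, x$tau))
  cat(sprintf("  Death rates:    delta_H0 = %g, delta_M0 = %g, delta_L0 = %g day^-1\n",
              x$delta_H0, x$delta_M0, x$delta_L0))
  cat(sprintf("  Daughters:      alpha_M = %g, alpha_L = %g; K_M = %g, K_L = %g cells\n",
              x$alpha_M, x$alpha_L, x$K_M, x$K_L))
  invisible(x)
}

#' Update selected fields of a parameter set
#'
#' Rebuilds an [hsc_params()] object with the given fields replaced, so the
#' derived `r2` and all invariants are re-validated. `r2` itself cannot be
#' set; change `rho` (or `r1`) instead.
#'
#' @param params an `hsc_params` object.
#' @param ... named replacement values among the [hsc_params()] arguments.
#' @return A new `hsc_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "hsc_params"))
  repl <- list(...)
  if (length(repl)) {
    bad <- setdiff(names(repl), setdiff(names(params), "r2"))
    if ("r2" %in% names(repl))
      stop("r2 is derived from rho * r1 and cannot be set directly",
           call. = FALSE)
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  args <- params[setdiff(names(params), "r2")]
  args[names(repl)] <- repl
  do.call(hsc_params, args)
}

# Parameter vector in the order the compiled integrator expects.
.pack_params <- function(p) {
  c(p$r1, p$r2, p$h1, p$h2, p$K_H, p$gamma, p$phi,
    p$delta_H0, p$delta_M0, p$delta_L0, p$alpha_M, p$alpha_L,
    p$tau, p$K_M, p$K_L)
}

#' Niche degradation schedule
#'
#' The degradation increment Delta (day^-1) added to all three baseline
#' death rates, representing aging-related decline of the bone-marrow niche.
#' Either constant over the whole simulation or, to model growth-factor
#' support that restores the niche, dropped to zero (Heaviside) after a
#' treatment time.
#'
#' @param delta degradation increment Delta (day^-1), `>= 0`.
#' @param treatment_time optional time (days) after which Delta becomes 0;
#'   `NULL` means Delta is constant throughout.
#' @return An object of class `niche_schedule`.
#' @examples
#' sched <- niche_schedule(0.05, treatment_time = 15)
#' delta_at(sched, c(10, 15, 20))  # 0.05 0.05 0.00
#' @export
niche_schedule <- function(delta = 0, treatment_time = NULL) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0)
    stop("delta must be a single finite number >= 0", call. = FALSE)
  if (!is.null(treatment_time)) {
    if (!is.numeric(treatment_time) || length(treatment_time) != 1L ||
        !is.finite(treatment_time) || treatment_time < 0)
      stop("treatment_time must be a single finite number >= 0",
           call. = FALSE)
  }
  structure(list(delta = delta, treatment_time = treatment_time),
            class = "niche_schedule")
}

#' Evaluate a niche schedule
#'
#' @param schedule a [niche_schedule()].
#' @param t times (days), vectorized.
#' @return Delta(t): `delta` for `t <= treatment_time` (or everywhere when no
#'   treatment time is set), 0 afterward.
#' @export
delta_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "niche_schedule"))
  if (is.null(schedule$treatment_time)) rep(schedule$delta, length(t))
  else ifelse(t <= schedule$treatment_time, schedule$delta, 0)
}

#' @export
print.niche_schedule <- function(x, ...) {
  if (is.null(x$treatment_time))
    cat(sprintf("Niche schedule: Delta = %g day^-1 (constant)\n", x$delta))
  else
    cat(sprintf("Niche schedule: Delta = %g day^-1, dropped to 0 after t = %g d\n",
                x$delta, x$treatment_time))
  invisible(x)
}
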