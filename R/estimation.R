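#' Healthy homeostatic reference total
#'
#' Total HSC count at homeostasis in a healthy system: the repopulation
#' protocol at symmetric baseline competition (`h1 = h2 = 1`), no growth
#' disparity (`rho = 1`) and an undamaged niche (`Delta = 0`). With default
#' parameters this is close to `K_H * (1 - delta_H0 / r1)` because demand is
#' negligible at homeostasis.
#'
#' @param params an [hsc_params()] object; competition and growth asymmetry
#'   are overridden to the healthy values.
#' @param ... further arguments passed to [simulate_repopulation()].
#' @return Final total HSC count (cells).
#' @export
healthy_reference_total <- function(params = hsc_params(), ...) {
  p <- update_params(params, h1 = 1, h2 = 1, rho = 1)
  simulate_repopulation(p, niche = niche_schedule(0), ...)$summary$H_total
}

#' Infer competition intensity from a homeostatic decline
#'
#' Inverts the model: given the surviving fraction of the healthy
#' homeostatic HSC total (e.g. 0.20 after an 80% decline) and an assumed
#' niche degradation increment Delta, finds the symmetric competition
#' coefficient `h1 = h2 = h` whose full repopulation simulation ends at the
#' target total. Uses bisection on h, relying on (and asserting) the
#' monotone decrease of the homeostatic total in h; the bracket is expanded
#' geometrically if it does not straddle the target.
#'
#' @param observed_fraction surviving fraction of the healthy homeostatic
#'   total, in (0, 1\].
#' @param delta assumed degradation increment (day^-1, default 0; the
#'   uncompromised-marrow convention).
#' @param params baseline [hsc_params()].
#' @param tol relative tolerance on the achieved total (default 1e-3).
#' @param h_bracket initial bisection bracket for h.
#' @param baseline `"simulated"` (default) measures the healthy reference by
#'   simulation; `"capacity"` uses `K_H` instead.
#' @param ... further arguments passed to [simulate_repopulation()].
#' @return An object of class `competition_fit` with the inferred `h`,
#'   reference and target totals, achieved total, iteration count and
#'   residual. Accessors: [coef()], [summary()], [predict()].
#' @examples
#' \donttest{
#' fit <- infer_competition(0.20, step = 0.05)
#' coef(fit)  # close to 9 with the simulated baseline
#' }
#' @export
infer_competition <- function(observed_fraction, delta = 0,
                              params = hsc_params(), tol = 1e-3,
                              h_bracket = c(1e-3, 50),
                              baseline = c("simulated", "capacity"), ...) {
  baseline <- match.arg(baseline)
  if (!is.numeric(observed_fraction) || length(observed_fraction) != 1L ||
      observed_fraction <= 0 || observed_fraction > 1)
    stop("observed_fraction must lie in (0, 1]", call. = FALSE)
  stopifnot(delta >= 0, length(h_bracket) == 2L, h_bracket[1] < h_bracket[2])
  reference <- if (baseline == "simulated")
    healthy_reference_total(params, ...) else params$K_H
  target <- observed_fraction * reference
  total_at <- function(h) {
    p <- update_params(params, h1 = h, h2 = h, rho = 1)
    simulate_repopulation(p, niche = niche_schedule(delta), ...)$summary$H_total
  }
  n_sim <- 0L
  lo <- h_bracket[1]; hi <- h_bracket[2]
  f_lo <- total_at(lo); f_hi <- total_at(hi); n_sim <- n_sim + 2L
  # homeostatic total decreases in h: f_lo is the ceiling, f_hi the floor
  expansions <- 0L
  while (f_hi > target && expansions < 10L) {
    hi <- hi * 2; f_hi <- total_at(hi); n_sim <- n_sim + 1L
    expansions <- expansions + 1L
  }
  if (f_lo < target || f_hi > target)
    stop(sprintf(paste0("target total %.4g cells not bracketed: achievable ",
                        "range [%.4g, %.4g] for h in [%g, %g] at Delta = %g"),
                 target, f_hi, f_lo, lo, hi, delta), call. = FALSE)
  iter <- 0L
  f_mid <- NA_real_; mid <- NA_real_
  repeat {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    f_mid <- total_at(mid); n_sim <- n_sim + 1L
    if (f_mid > f_lo + 1e-6 * max(1, f_lo) ||
        f_mid < f_hi - 1e-6 * max(1, f_hi))
      stop("homeostatic total is not monotone in h on the bracket; ",
           "bisection aborted", call. = FALSE)
    if (abs(f_mid - target) / target < tol || (hi - lo) < 1e-10) break
    if (f_mid > target) { lo <- mid; f_lo <- f_mid }
    else { hi <- mid; f_hi <- f_mid }
    if (iter >= 200L)
      stop("bisection failed to converge", call. = FALSE)
  }
  structure(list(h = mid, observed_fraction = observed_fraction,
                 delta = delta, reference = reference, target = target,
                 achieved = f_mid, baseline = baseline,
                 residual = abs(f_mid - target) / target,
                 iterations = iter, n_sim = n_sim, params = params,
                 tol = tol, sim_args = list(...)),
            class = "competition_fit")
}

#' Fit competition intensity to a two-group stem-cell cohort
#'
#' The headline model-fitting interface: takes young/old stem-cell counts
#' (a [generate_cohort()] sample or two numeric vectors), estimates the
#' fractional decline of the old-group mean relative to the young-group
#' mean, tests it with Welch's unequal-variances t-test, and inverts the
#' repopulation model to the symmetric competition coefficient h that
#' reproduces the surviving fraction at the assumed niche damage.
#'
#' @param young young-group counts (cells), or a `cohort_sample`.
#' @param old old-group counts; ignored when `young` is a `cohort_sample`.
#' @param delta assumed degradation increment (day^-1, default 0).
#' @param params baseline [hsc_params()].
#' @param ... further arguments passed to [infer_competition()].
#' @return A `competition_fit` additionally carrying the decline estimate
#'   and the Welch test.
#' @examples
#' \donttest{
#' coh <- generate_cohort(young_mean = 10000, fractional_decline = 0.8,
#'                        seed = 1)
#' fit <- fit_competition(coh, step = 0.05)
#' summary(fit)
#' }
#' @export
fit_competition <- function(young, old = NULL, delta = 0,
                            params = hsc_params(), ...) {
  if (inherits(young, "cohort_sample")) {
    sample <- young
  } else {
    stopifnot(is.numeric(young), is.numeric(old))
    sample <- structure(list(young = young, old = old, settings = NULL),
                        class = "cohort_sample")
  }
  decline <- fractional_decline_estimate(sample)
  if (decline <= 0 || decline >= 1)
    stop("estimated decline ", signif(decline, 3),
         " is outside (0, 1); cannot invert the model", call. = FALSE)
  test <- welch_t_test(sample$young, sample$old)
  fit <- infer_competition(1 - decline, delta = delta, params = params, ...)
  fit$decline <- decline
  fit$welch <- test
  fit$sample <- sample
  fit
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Inferred inter-clonal competition intensity\n")
  if (!is.null(x$decline))
    cat(sprintf("  Cohort decline: %.1f%% (Welch t = %.3g, df = %.3g, p = %.3g)\n",
                100 * x$decline, x$welch$statistic, x$welch$df, x$welch$p.value))
  cat(sprintf("  Surviving fraction %.3g of healthy reference %.4g cells (%s baseline)\n",
              x$observed_fraction, x$reference, x$baseline))
  cat(sprintf("  Assumed Delta = %g day^-1\n", x$delta))
  cat(sprintf("  h1 = h2 = %.4g  (achieved %.4g vs target %.4g cells, rel. residual %.2g)\n",
              x$h, x$achieved, x$target, x$residual))
  invisible(x)
}

#' @export
coef.competition_fit <- function(object, ...) {
  c(h = object$h)
}

#' @export
summary.competition_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  Bisection: %d iterations, %d simulations, tolerance %g\n",
              object$iterations, object$n_sim, object$tol))
  cf <- zero_demand_hsc_fixed_point(
    update_params(object$params, h1 = object$h, h2 = object$h, rho = 1),
    object$delta)
  cat(sprintf("  Zero-demand closed form at fitted h: total %.4g cells (%s)\n",
              cf$total, cf$type))
  invisible(object)
}

#' Predicted homeostatic totals from a competition fit
#'
#' Runs the repopulation model at the fitted symmetric competition intensity
#' over a set of niche degradation increments and returns the predicted
#' homeostatic HSC totals.
#'
#' @param object a `competition_fit`.
#' @param delta degradation increments (day^-1); defaults to the fit's value.
#' @param ... further arguments passed to [simulate_repopulation()].
#' @return A data frame with columns `delta` and `H_total`.
#' @export
predict.competition_fit <- function(object, delta = object$delta, ...) {
  p <- update_params(object$params, h1 = object$h, h2 = object$h, rho = 1)
  args <- if (length(list(...))) list(...) else object$sim_args
  H <- vapply(delta, function(d) {
    do.call(simulate_repopulation,
            c(list(params = p, niche = niche_schedule(d)), args))$summary$H_total
  }, numeric(1))
  data.frame(delta = delta, H_total = H)
}

#' Decline contour in the (Delta, h) plane
#'
#' For each niche degradation increment on a grid, infers the symmetric
#' competition coefficient that reproduces the observed surviving fraction:
#' the locus of (Delta, h) combinations consistent with one observed
#' homeostatic decline. Grid points whose damage alone already drives the
#' total below the target (no h can match) are reported as infeasible.
#'
#' @param observed_fraction surviving fraction in (0, 1\].
#' @param delta_grid degradation increments to scan (day^-1).
#' @param params baseline [hsc_params()].
#' @param ... further arguments passed to [infer_competition()].
#' @return A data frame with columns `delta`, `h` (NA when infeasible),
#'   `feasible`, and `reason` for infeasible points.
#' @export
decline_contour <- function(observed_fraction,
                            delta_grid = seq(0, 0.1, by = 0.01),
                            params = hsc_params(), ...) {
  rows <- lapply(delta_grid, function(d) {
    fit <- tryCatch(infer_competition(observed_fraction, delta = d,
                                      params = params, ...),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      message("Delta = ", d, " infeasible: ", conditionMessage(fit))
      data.frame(delta = d, h = NA_real_, feasible = FALSE,
                 reason = conditionMessage(fit))
    } else {
      data.frame(delta = d, h = fit$h, feasible = TRUE, reason = "")
    }
  })
  out <- do.call(rbind, rows)
  if (!any(out$feasible))
    warning("contour is empty: no Delta on the grid can reach the target")
  out
}
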