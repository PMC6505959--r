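#' Summarize a repopulation run at homeostasis
#'
#' Homeostasis is taken operationally as the state at the end of the run.
#' The summary records the final state, clone totals, the mutant/healthy
#' clonal ratio, the differentiation demand D, and an extinction flag (total
#' HSCs below the criterion). Clones below a small-population floor are
#' treated as absent, so the ratio is 0 (mutant gone), `Inf` (healthy gone)
#' or `NaN` (both gone). A settling check flags runs whose relative change
#' over the last 10 days exceeds `1e-4`.
#'
#' @param traj an `hsc_trajectory`.
#' @param extinction_criterion HSC total (cells) below which the system is
#'   scored extinct (default 10).
#' @param floor clone size (cells) below which a clone counts as absent in
#'   the ratio (default 1e-6).
#' @return An object of class `steady_state_summary`.
#' @export
steady_state_summary <- function(traj, extinction_criterion = 10,
                                 floor = 1e-6) {
  stopifnot(inherits(traj, "hsc_trajectory"))
  n <- length(traj$time)
  fin <- traj$state[n, ]
  H1 <- fin[["H1"]]; H2 <- fin[["H2"]]
  h1f <- if (H1 < floor) 0 else H1
  h2f <- if (H2 < floor) 0 else H2
  sig <- demand_signals(fin[["M1"]] + fin[["M2"]], fin[["L1"]] + fin[["L2"]],
                        traj$params)
  t_end <- traj$time[n]
  settled <- NA
  if (t_end > 10) {
    prev <- state_at(traj, t_end - 10)
    rel <- abs(fin - prev) / pmax(abs(fin), 1)
    settled <- max(rel) <= 1e-4
  }
  out <- list(
    final = fin, t_end = t_end,
    H_total = H1 + H2,
    M_total = fin[["M1"]] + fin[["M2"]],
    L_total = fin[["L1"]] + fin[["L2"]],
    ratio = h2f / h1f,
    D = differentiation_demand(sig, traj$params),
    extinct = (H1 + H2) < extinction_criterion,
    extinction_criterion = extinction_criterion,
    settled = settled
  )
  class(out) <- "steady_state_summary"
  out
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf("Homeostasis at t = %g d:\n", x$t_end))
  cat(sprintf("  HSC total %.4g cells (H1 = %.4g, H2 = %.4g; H2/H1 = %.4g)\n",
              x$H_total, x$final[["H1"]], x$final[["H2"]], x$ratio))
  cat(sprintf("  Myeloid %.4g, lymphoid %.4g cells; demand D = %.3g /d\n",
              x$M_total, x$L_total, x$D))
  cat(sprintf("  Extinct (< %g HSCs): %s; settled: %s\n",
              x$extinction_criterion, x$extinct, x$settled))
  invisible(x)
}

#' Simulate post-transplant repopulation
#'
#' Integrates the system from a myeloablated, freshly seeded marrow: every
#' compartment (both clones, HSC, myeloid, lymphoid) starts at `seed_cells`,
#' with the same constant value as pre-simulation history, and runs to
#' `t_end` where the homeostatic state is summarized.
#'
#' @param params an [hsc_params()] object.
#' @param niche a [niche_schedule()].
#' @param seed_cells cells seeded per compartment (default 100).
#' @param t_end horizon (days, default 280 -- long enough to settle).
#' @param step integration step (days, default 0.01).
#' @param extinction_criterion see [steady_state_summary()].
#' @return A list with components `trajectory` (`hsc_trajectory`) and
#'   `summary` (`steady_state_summary`).
#' @examples
#' \donttest{
#' rec <- simulate_repopulation(hsc_params(), step = 0.05)
#' rec$summary
#' }
#' @export
simulate_repopulation <- function(params, niche = niche_schedule(),
                                  seed_cells = 100, t_end = 280,
                                  step = 0.01, extinction_criterion = 10) {
  if (!is.numeric(seed_cells) || length(seed_cells) != 1L || seed_cells < 0)
    stop("seed_cells must be a single number >= 0", call. = FALSE)
  traj <- dde_integrate(params, history = seed_cells, niche = niche,
                        t_end = t_end, step = step)
  list(trajectory = traj,
       summary = steady_state_summary(traj, extinction_criterion))
}

.sweep_row <- function(summ, a1, a2) {
  data.frame(axis1 = a1, axis2 = a2,
             H1 = summ$final[["H1"]], H2 = summ$final[["H2"]],
             M1 = summ$final[["M1"]], M2 = summ$final[["M2"]],
             L1 = summ$final[["L1"]], L2 = summ$final[["L2"]],
             H_total = summ$H_total, M_total = summ$M_total,
             L_total = summ$L_total, ratio = summ$ratio, D = summ$D,
             extinct = summ$extinct)
}

#' Sweep competition intensity and relative growth rate
#'
#' Repeats the repopulation protocol over a grid of symmetric competition
#' intensities (`h1 = h2 = h`) and relative mutant growth rates `rho`,
#' recording the homeostatic summary in each cell. The (h = 1, rho = 1)
#' cell is the healthy-patient reference.
#'
#' @param h_values symmetric competition intensities (default 25 points on
#'   \[0.25, 3\]).
#' @param rho_values relative mutant growth rates (default 25 points on
#'   \[0.25, 3\]).
#' @param params baseline [hsc_params()]; its `h1`, `h2`, `rho` are
#'   overridden cell by cell.
#' @param niche a [niche_schedule()] shared by all cells.
#' @param ... further arguments passed to [simulate_repopulation()].
#' @return An object of class `hsc_sweep`: a long-format data frame with
#'   axis columns `h`, `rho`, the final per-clone populations, totals,
#'   mutant/healthy ratio, demand `D` and `extinct` flag.
#' @export
competition_growth_sweep <- function(h_values = seq(0.25, 3, length.out = 25),
                                     rho_values = seq(0.25, 3, length.out = 25),
                                     params = hsc_params(),
                                     niche = niche_schedule(), ...) {
  stopifnot(all(h_values >= 0), all(rho_values > 0))
  rows <- vector("list", length(h_values) * length(rho_values))
  i <- 0L
  for (rho in rho_values) {
    for (h in h_values) {
      p <- update_params(params, h1 = h, h2 = h, rho = rho)
      rec <- simulate_repopulation(p, niche = niche, ...)
      i <- i + 1L
      rows[[i]] <- .sweep_row(rec$summary, h, rho)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c("h", "rho")
  structure(out, class = c("hsc_sweep", "data.frame"),
            axes = c("h", "rho"))
}

#' Sweep niche damage and competition intensity
#'
#' Repopulation over a grid of constant degradation increments Delta and
#' symmetric competition intensities h (`rho` fixed at the baseline value),
#' recording homeostatic totals and extinction flags.
#'
#' @param delta_values degradation increments (day^-1; default 21 points on
#'   \[0, 0.2\]).
#' @param h_values symmetric competition intensities (default 25 points on
#'   \[0.25, 3\]).
#' @param params baseline [hsc_params()].
#' @param ... further arguments passed to [simulate_repopulation()].
#' @return An `hsc_sweep` data frame with axis columns `delta`, `h`.
#' @export
niche_damage_sweep <- function(delta_values = seq(0, 0.2, length.out = 21),
                               h_values = seq(0.25, 3, length.out = 25),
                               params = hsc_params(), ...) {
  stopifnot(all(delta_values >= 0), all(h_values >= 0))
  rows <- vector("list", length(delta_values) * length(h_values))
  i <- 0L
  for (h in h_values) {
    for (delta in delta_values) {
      p <- update_params(params, h1 = h, h2 = h)
      rec <- simulate_repopulation(p, niche = niche_schedule(delta), ...)
      i <- i + 1L
      rows[[i]] <- .sweep_row(rec$summary, delta, h)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1:2] <- c("delta", "h")
  structure(out, class = c("hsc_sweep", "data.frame"),
            axes = c("delta", "h"))
}

#' @export
print.hsc_sweep <- function(x, ...) {
  ax <- attr(x, "axes")
  cat(sprintf("Steady-state sweep over (%s, %s): %d x %d grid\n",
              ax[1], ax[2], length(unique(x[[ax[1]]])),
              length(unique(x[[ax[2]]]))))
  cat(sprintf("  H_total range %.4g - %.4g cells; %d extinct cell(s)\n",
              min(x$H_total), max(x$H_total), sum(x$extinct)))
  invisible(x)
}

#' @export
plot.hsc_sweep <- function(x, value = "H_total", ...) {
  ax <- attr(x, "axes")
  a1 <- sort(unique(x[[ax[1]]])); a2 <- sort(unique(x[[ax[2]]]))
  z <- matrix(x[[value]][order(x[[ax[2]]], x[[ax[1]]])],
              nrow = length(a1), ncol = length(a2))
  graphics::image(a1, a2, z, xlab = ax[1], ylab = ax[2],
                  main = value, ...)
  graphics::contour(a1, a2, z, add = TRUE)
  invisible(x)
}

#' Write a sweep to CSV
#'
#' @param sweep an `hsc_sweep`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "hsc_sweep"))
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Locate the extinction threshold in niche damage
#'
#' Finds the smallest degradation increment Delta at which the repopulation
#' protocol ends below the extinction criterion: a coarse upward scan over
#' `delta_grid` brackets the transition, then bisection refines it to `tol`.
#' Reported is the lower edge of extinction, i.e. the infimum Delta with
#' final HSC total < criterion.
#'
#' @param params an [hsc_params()] object (competition is taken from it;
#'   the healthy default has `h1 = h2 = 1`).
#' @param delta_grid increasing coarse grid of Delta values (day^-1).
#' @param criterion extinction criterion (cells, default 10).
#' @param tol bisection tolerance on Delta (day^-1, default 1e-3).
#' @param ... further arguments passed to [simulate_repopulation()].
#' @return A list with `threshold` (Delta*, day^-1), the bracketing grid
#'   values, and the number of simulations used; `threshold` is `NA` with a
#'   message element when no grid value goes extinct.
#' @export
find_extinction_threshold <- function(params = hsc_params(),
                                      delta_grid = seq(0, 0.2, by = 0.01),
                                      criterion = 10, tol = 1e-3, ...) {
  stopifnot(length(delta_grid) >= 2, !is.unsorted(delta_grid))
  final_H <- function(delta) {
    simulate_repopulation(params, niche = niche_schedule(delta),
                          extinction_criterion = criterion, ...)$summary$H_total
  }
  n_sim <- 0L
  hi <- NA_real_; lo <- delta_grid[1]
  for (delta in delta_grid) {
    n_sim <- n_sim + 1L
    if (final_H(delta) < criterion) { hi <- delta; break }
    lo <- delta
  }
  if (is.na(hi)) {
    return(list(threshold = NA_real_, bracket = range(delta_grid),
                n_sim = n_sim, message = "no threshold in range"))
  }
  if (hi == delta_grid[1]) {
    return(list(threshold = hi, bracket = c(hi, hi), n_sim = n_sim,
                message = "extinct at the lower end of the grid"))
  }
  bracket <- c(lo, hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    n_sim <- n_sim + 1L
    if (final_H(mid) < criterion) hi <- mid else lo <- mid
  }
  list(threshold = (lo + hi) / 2, bracket = bracket, n_sim = n_sim)
}

#' Growth-factor intervention experiment
#'
#' Compares three repopulation runs into damaged marrow: untreated (Delta
#' constant), treated (Delta dropped to 0 at the treatment time, modelling
#' growth-factor restoration of the niche), and the healthy reference
#' (Delta = 0 throughout), all otherwise identical.
#'
#' @param params an [hsc_params()] object.
#' @param delta degradation increment before treatment (day^-1).
#' @param treatment_time day at which the niche is restored (default 15).
#' @param t_end horizon (days, default 280).
#' @param ... further arguments passed to [simulate_repopulation()].
#' @return An object of class `gf_intervention`: list of the three
#'   `steady_state_summary` objects (`untreated`, `treated`, `healthy`) and
#'   the settings used.
#' @export
growth_factor_intervention <- function(params, delta, treatment_time = 15,
                                       t_end = 280, ...) {
  stopifnot(delta >= 0)
  untreated <- simulate_repopulation(params, niche_schedule(delta),
                                     t_end = t_end, ...)
  treated <- simulate_repopulation(params,
                                   niche_schedule(delta, treatment_time),
                                   t_end = t_end, ...)
  healthy <- simulate_repopulation(params, niche_schedule(0),
                                   t_end = t_end, ...)
  structure(list(untreated = untreated$summary, treated = treated$summary,
                 healthy = healthy$summary, delta = delta,
                 treatment_time = treatment_time),
            class = "gf_intervention")
}

#' @export
print.gf_intervention <- function(x, ...) {
  cat(sprintf("Growth-factor intervention (Delta = %g /d, treated at day %g)\n",
              x$delta, x$treatment_time))
  m <- rbind(untreated = c(x$untreated$H_total, x$untreated$M_total,
                           x$untreated$L_total),
             treated = c(x$treated$H_total, x$treated$M_total,
                         x$treated$L_total),
             healthy = c(x$healthy$H_total, x$healthy$M_total,
                         x$healthy$L_total))
  colnames(m) <- c("HSC", "myeloid", "lymphoid")
  print(signif(m, 4))
  invisible(x)
}

#' Differentiation demand at homeostasis
#'
#' Evaluates the demand D from the final state of a trajectory: a measure of
#' how far the mature compartments sit below their capacities at steady
#' state (D near 0 when daughters are plentiful, up to `gamma` when empty).
#'
#' @param traj an `hsc_trajectory`.
#' @param params parameters; defaults to those stored on the trajectory.
#' @return D (day^-1).
#' @export
demand_at_homeostasis <- function(traj, params = traj$params) {
  stopifnot(inherits(traj, "hsc_trajectory"))
  n <- length(traj$time)
  fin <- traj$state[n, ]
  sig <- demand_signals(fin[["M1"]] + fin[["M2"]], fin[["L1"]] + fin[["L2"]],
                        params)
  differentiation_demand(sig, params)
}
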