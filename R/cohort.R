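#' Generate a synthetic young/old stem-cell cohort
#'
#' Draws two groups of positive stem-cell counts emulating FACS-derived LSK
#' measurements from young and aged mice: each group is log-normal with a
#' specified arithmetic mean and coefficient of variation, the old-group
#' mean being the young mean reduced by the fractional decline. Counts are
#' positive by construction (multiplicative biological variability);
#' `cv = 0` is the degenerate constant-count limit.
#'
#' @param n_young,n_old group sizes (default 5 and 6).
#' @param young_mean arithmetic mean count of the young group (cells).
#' @param fractional_decline fraction in (0, 1); the old-group mean is
#'   `young_mean * (1 - fractional_decline)`.
#' @param cv_young,cv_old within-group coefficients of variation
#'   (sd/mean; default 0.15, LSK-like; ~0.5 mimics the noisier LSK-SLAM
#'   gate).
#' @param seed optional integer seed; the draw is reproducible given the
#'   same settings and seed, and the caller's RNG state is left untouched.
#' @return An object of class `cohort_sample`: list with `young` and `old`
#'   count vectors and the generator `settings`.
#' @examples
#' coh <- generate_cohort(fractional_decline = 0.8, seed = 42)
#' fractional_decline_estimate(coh)
#' @export
generate_cohort <- function(n_young = 5, n_old = 6, young_mean = 10000,
                            fractional_decline = 0.8, cv_young = 0.15,
                            cv_old = 0.15, seed = NULL) {
  stopifnot(n_young >= 2, n_old >= 2, young_mean > 0,
            cv_young >= 0, cv_old >= 0)
  if (fractional_decline <= 0 || fractional_decline >= 1)
    stop("fractional_decline must lie in (0, 1)", call. = FALSE)
  old_mean <- young_mean * (1 - fractional_decline)
  draw <- function(n, m, cv) {
    if (cv == 0) return(rep(m, n))
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(m) - sdlog^2 / 2  # arithmetic mean m, CV cv
    stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
  }
  runner <- function() {
    list(young = draw(n_young, young_mean, cv_young),
         old = draw(n_old, old_mean, cv_old))
  }
  counts <- if (is.null(seed)) runner() else .with_seed(seed, runner())
  structure(list(young = counts$young, old = counts$old,
                 settings = list(n_young = n_young, n_old = n_old,
                                 young_mean = young_mean,
                                 fractional_decline = fractional_decline,
                                 cv_young = cv_young, cv_old = cv_old,
                                 seed = seed)),
            class = "cohort_sample")
}

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf("Synthetic stem-cell cohort: %d young, %d old\n",
              length(x$young), length(x$old)))
  cat(sprintf("  Young mean %.4g, old mean %.4g cells (decline estimate %.1f%%)\n",
              mean(x$young), mean(x$old),
              100 * fractional_decline_estimate(x)))
  invisible(x)
}

#' Fractional decline estimate
#'
#' The decline of the old-group mean relative to the young-group mean,
#' `1 - mean(old) / mean(young)`: 0 for identical groups, 0.8 for an 80%
#' decline, negative (growth) when the old mean exceeds the young mean.
#'
#' @param sample a `cohort_sample` (or a list with `young` and `old`
#'   numeric vectors).
#' @return The estimated fractional decline (dimensionless, `< 1`).
#' @export
fractional_decline_estimate <- function(sample) {
  stopifnot(is.numeric(sample$young), is.numeric(sample$old),
            length(sample$young) >= 1, length(sample$old) >= 1)
  est <- 1 - mean(sample$old) / mean(sample$young)
  if (est < 0)
    message("old-group mean exceeds the young-group mean (growth, not decline)")
  est
}

#' Welch's unequal-variances t-test
#'
#' Two-sided comparison of two group means without assuming equal
#' variances: `t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)` with
#' Welch-Satterthwaite degrees of freedom. Thin wrapper around
#' [stats::t.test()] returning the three quantities of interest.
#'
#' @param young,old numeric vectors, each with at least 2 values and not
#'   both of zero variance.
#' @return A list with `statistic` (t), `df` (Welch-Satterthwaite) and
#'   `p.value` (two-sided).
#' @examples
#' welch_t_test(c(10, 12, 14), c(1, 2, 3))
#' @export
welch_t_test <- function(young, old) {
  stopifnot(is.numeric(young), is.numeric(old),
            length(young) >= 2, length(old) >= 2)
  if (stats::var(young) == 0 && stats::var(old) == 0)
    stop("both groups have zero variance; the Welch statistic is undefined",
         call. = FALSE)
  tt <- stats::t.test(young, old, var.equal = FALSE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value)
}

#' Write / read a cohort as two-column delimited text
#'
#' Plain-text exchange format: columns `group` (`young`/`old`) and `count`
#' (cells).
#'
#' @param sample a `cohort_sample`.
#' @param path file path.
#' @return `write_cohort`: `path`, invisibly. `read_cohort`: a
#'   `cohort_sample` (without generator settings).
#' @export
write_cohort <- function(sample, path) {
  stopifnot(inherits(sample, "cohort_sample"))
  df <- data.frame(group = c(rep("young", length(sample$young)),
                             rep("old", length(sample$old))),
                   count = c(sample$young, sample$old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "count") %in% names(df)))
    stop("cohort file must have columns 'group' and 'count'", call. = FALSE)
  if (!all(df$group %in% c("young", "old")))
    stop("group column must contain only 'young' and 'old'", call. = FALSE)
  structure(list(young = df$count[df$group == "young"],
                 old = df$count[df$group == "old"], settings = NULL),
            class = "cohort_sample")
}
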