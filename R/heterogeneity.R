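#' Subgroup survival-RDD analysis
#'
#' Runs the full stratified-hazard / risk-difference pipeline separately on
#' each non-missing level of a factor (child birthweight, partnership status,
#' family education, income), plus a Wald test for a different effect across
#' subgroups at each horizon based on the simulation draws.  Levels labelled
#' `"missing"` (or `NA`) are reported separately and excluded from the test.
#'
#' @param cohort An `analysis_cohort`.
#' @param factor_name Name of the grouping column.
#' @param horizons,n_sims Passed to [estimate_risk_differences()].
#' @param seed Integer seed; each level uses a deterministic offset of it.
#' @param ... Passed to [fit_hazard_model()].
#' @return An object of class `subgroup_result`: list with `factor_name`,
#'   `levels` (named list of `risk_difference_table`s), `test` (data.frame of
#'   per-horizon statistic, df, p-value), `n_by_level`, `missing_n`.
#' @export
subgroup_rdd <- function(cohort, factor_name, horizons = seq(5, 30, by = 5),
                         n_sims = 2000, seed = 1L, ...) {
  x <- as.character(cohort[[factor_name]])
  missing_lev <- is.na(x) | x == "missing"
  levs <- unique(x[!missing_lev])
  if (length(levs) < 2)
    stop("factor '", factor_name, "' needs at least 2 non-missing levels",
         call. = FALSE)
  levs <- levs[order(match(levs, levels(cohort[[factor_name]])))]

  results <- list()
  for (i in seq_along(levs)) {
    sub <- cohort[!missing_lev & x == levs[i], , drop = FALSE]
    class(sub) <- c("analysis_cohort", "data.frame")
    fit <- fit_hazard_model(sub, ...)
    results[[levs[i]]] <- estimate_risk_differences(
      fit, horizons, n_sims = n_sims, seed = derive_seed(seed, i))
  }
  test <- do.call(rbind, lapply(seq_along(horizons), function(j) {
    draws <- lapply(results, function(r) attr(r, "draws")[j, ])
    tst <- interaction_test(draws)
    data.frame(horizon = horizons[j], statistic = tst$statistic,
               df = tst$df, p_value = tst$p_value)
  }))
  structure(list(factor_name = factor_name, levels = results, test = test,
                 n_by_level = table(x[!missing_lev]),
                 missing_n = sum(missing_lev)),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat("Subgroup analysis by", x$factor_name, "\n")
  for (l in names(x$levels)) {
    rd5 <- x$levels[[l]][1, ]
    cat(sprintf("  %-14s n=%6d  RD@%gy %.1f fewer/1000 (%.1f to %.1f)\n",
                l, x$n_by_level[[l]], rd5$horizon, rd5$rd_per_1000,
                rd5$ci_low, rd5$ci_high))
  }
  p5 <- x$test$p_value[1]
  cat(sprintf("  test for different effect across subgroups at %g y: p = %.3f\n",
              x$test$horizon[1], p5))
  invisible(x)
}

#' Wald test for different risk differences across subgroup levels
#'
#' Operates on the simulation draws of the horizon risk difference so the
#' test matches the reported estimand.  Level means and variances are taken
#' from the draws (independent across levels); for two levels this is a
#' z-test on the difference, for L levels a chi-square test on the L-1
#' contrasts against the last level.
#'
#' @param draws_by_level Named list of numeric draw vectors, one per level.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
interaction_test <- function(draws_by_level) {
  L <- length(draws_by_level)
  if (L < 2) stop("need at least 2 levels with draws", call. = FALSE)
  m <- vapply(draws_by_level, mean, numeric(1))
  v <- vapply(draws_by_level, stats::var, numeric(1))
  d <- m[-L] - m[L]
  if (all(d == 0)) return(list(statistic = 0, df = L - 1L, p_value = 1))
  Sigma <- diag(v[-L], L - 1L) + v[L]
  stat <- as.numeric(t(d) %*% solve(Sigma, d))
  list(statistic = stat, df = L - 1L,
       p_value = stats::pchisq(stat, df = L - 1L, lower.tail = FALSE))
}

#' Placebo-reform sweep
#'
#' Re-runs the design at cut-off dates where no reform happened.  To avoid
#' contamination by the true treatment effect, the analysis window is by
#' default restricted to the side of the true cut-off containing the placebo
#' date (pre-reform placebos use only control births, post-reform placebos
#' only eligible births).  A nonzero placebo "effect" signals confounded
#' secular trends.
#'
#' @param cohort An `analysis_cohort` built with the true reform.
#' @param placebo_cutoffs Vector of placebo cut-off dates.
#' @param horizon Horizon (years) of the reported risk difference.
#' @param n_sims,seed Simulation settings.
#' @param restrict `"side"` (default) restricts to the true-cut-off side of
#'   each placebo date; `"none"` uses the full window (the true cut-off must
#'   then coincide with the placebo for a valid contrast).
#' @param ... Passed to [fit_hazard_model()].
#' @return An object of class `robustness_sweep`: data.frame with one row
#'   per setting (`setting`, `rd_per_1000`, `ci_low`, `ci_high`, `n`,
#'   `events`).
#' @export
placebo_reforms <- function(cohort, placebo_cutoffs, horizon = 5,
                            n_sims = 2000, seed = 1L, restrict = "side", ...) {
  true_cutoff <- attr(cohort, "reform")$cutoff_date
  rows <- list()
  for (i in seq_along(placebo_cutoffs)) {
    pc <- as_date_strict(placebo_cutoffs[i])
    dat <- cohort
    if (restrict == "side" && pc != true_cutoff) {
      keep <- if (pc < true_cutoff) cohort$birth_date < true_cutoff
              else cohort$birth_date >= true_cutoff
      dat <- cohort[keep, , drop = FALSE]
    }
    if (!nrow(dat)) stop("no births around placebo cut-off ", format(pc),
                         call. = FALSE)
    dat$u <- years_between(pc, dat$birth_date)
    dat$treated <- as.integer(dat$birth_date >= pc)
    if (!any(dat$treated == 1) || !any(dat$treated == 0))
      stop("placebo cut-off ", format(pc),
           " has no births on one side within its window", call. = FALSE)
    class(dat) <- c("analysis_cohort", "data.frame")
    fit <- fit_hazard_model(dat, ...)
    rd <- estimate_risk_differences(fit, horizons = horizon, n_sims = n_sims,
                                    seed = derive_seed(seed, i))
    rows[[i]] <- data.frame(setting = format(pc),
                            rd_per_1000 = rd$rd_per_1000,
                            ci_low = rd$ci_low, ci_high = rd$ci_high,
                            n = nrow(dat), events = sum(dat$event),
                            stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            class = c("robustness_sweep", "data.frame"),
            sweep = "placebo", horizon = horizon, seed = seed)
}

#' Bandwidth-sensitivity sweep
#'
#' Recomputes the main risk-difference estimate over symmetric bandwidths
#' around the cut-off (default grid 12 to 45 months per side).
#'
#' @param cohort An `analysis_cohort`.
#' @param months_list Bandwidths in months per side.
#' @param horizon Horizon (years) of the reported risk difference.
#' @param n_sims,seed Simulation settings.
#' @param ... Passed to [fit_hazard_model()].
#' @return A `robustness_sweep` data.frame (one row per bandwidth).
#' @export
bandwidth_sweep <- function(cohort, months_list = c(12, 18, 24, 30, 36, 45),
                            horizon = 5, n_sims = 2000, seed = 1L, ...) {
  rows <- list()
  for (i in seq_along(months_list)) {
    bw <- months_list[i]
    dat <- restrict_bandwidth(cohort, bw)
    if (!sum(dat$event[dat$treated == 1]) || !sum(dat$event[dat$treated == 0]))
      stop("bandwidth ", bw, " months leaves no events on one side",
           call. = FALSE)
    fit <- fit_hazard_model(dat, ...)
    rd <- estimate_risk_differences(fit, horizons = horizon, n_sims = n_sims,
                                    seed = derive_seed(seed, i))
    rows[[i]] <- data.frame(setting = sprintf("%g months", bw),
                            months = bw,
                            rd_per_1000 = rd$rd_per_1000,
                            ci_low = rd$ci_low, ci_high = rd$ci_high,
                            n = nrow(dat), events = sum(dat$event),
                            stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, rows),
            class = c("robustness_sweep", "data.frame"),
            sweep = "bandwidth", horizon = horizon, seed = seed)
}

#' @export
print.robustness_sweep <- function(x, ...) {
  cat(sprintf("Robustness sweep (%s), %g-year risk difference per 1000:\n",
              attr(x, "sweep"), attr(x, "horizon")))
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}

#' ICD-era-adjusted fit
#'
#' Splits follow-up at the 1994 ICD-8 to ICD-10 transition, refits the
#' stratified hazard model with the era indicator as a time-dependent
#' covariate, and recomputes the risk-difference table.  Prediction at the
#' cut-off uses the era value implied by calendar time for a birth at the
#' cut-off date.
#'
#' @param cohort An `analysis_cohort` (unsplit; episodes are created here).
#' @param split_date Transition date (default 1994-01-01).
#' @param horizons,n_sims,seed Passed to [estimate_risk_differences()].
#' @param ... Passed to [fit_hazard_model()].
#' @return List with `fit` (a `survival_fit` including the `era`
#'   coefficient) and `rd` (a `risk_difference_table`).
#' @export
era_adjusted_fit <- function(cohort, split_date = "1994-01-01",
                             horizons = seq(5, 30, by = 5), n_sims = 2000,
                             seed = 1L, ...) {
  split_date <- as_date_strict(split_date)
  eps <- split_at_calendar_date(cohort, split_date)
  fit <- fit_hazard_model(eps, extras = "era", ...)
  cutoff <- attr(cohort, "reform")$cutoff_date
  t_era <- years_between(cutoff, split_date)  # era switches here for a
  profile <- function(times) {               # birth at the cut-off
    matrix(as.integer(times >= t_era), ncol = 1, dimnames = list(NULL, "era"))
  }
  rd <- estimate_risk_differences(fit, horizons, n_sims = n_sims, seed = seed,
                                  extras_profile = profile)
  list(fit = fit, rd = rd)
}
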