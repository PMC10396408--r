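#' Fit the stratified hazard model of the discontinuity design
#'
#' Proportional-hazards partial-likelihood fit with the reform groups
#' (control / eligible) as strata and years since birth as the time scale,
#' adjusting for a polynomial trend in the running variable `u` (years of
#' birth date since the cut-off; default linear plus squared, shared across
#' strata).  Ties are handled by the Breslow method; the coefficient
#' covariance is the cluster-robust sandwich aggregating score residuals by
#' mother; per-stratum baseline cumulative hazards (at `u = 0` and zero
#' extras, i.e. uncentred covariates) are computed by the Breslow estimator
#' together with Poisson-type increment variances used by the risk-difference
#' simulation.
#'
#' @param cohort An `analysis_cohort`, optionally in counting-process form
#'   (after [split_at_calendar_date()]).
#' @param trend_order Polynomial order of the running-variable trend (0-2;
#'   default 2: `u + u^2`).
#' @param extras Character vector of additional covariate columns (e.g.
#'   `"era"` after episode splitting).
#' @param side_specific Interact the trend terms with the treatment
#'   indicator (default FALSE, trends shared across strata as in standard
#'   practice for this design).
#' @param ties `"breslow"` (default, matches the baseline estimator) or
#'   `"efron"`.
#' @param cluster Cluster scores by `mother_id` (default TRUE); with
#'   singleton clusters this equals the unclustered robust variance.
#' @return An object of class `survival_fit`: coefficients, cluster-robust
#'   `vcov`, `naive_vcov`, per-stratum `baseline` step functions (`time`,
#'   `dLambda`, `var_dLambda`), counts, and the underlying `coxph` fit.
#' @export
fit_hazard_model <- function(cohort, trend_order = 2, extras = character(),
                             side_specific = FALSE, ties = "breslow",
                             cluster = TRUE) {
  episodes <- all(c("t_start", "t_stop") %in% names(cohort))
  for (g in c(0, 1))
    if (sum(cohort$event[cohort$treated == g]) < 1)
      stop("no events in stratum treated=", g, call. = FALSE)

  trend_terms <- switch(as.character(trend_order),
                        "0" = character(),
                        "1" = "u",
                        "2" = c("u", "I(u^2)"),
                        stop("trend_order must be 0, 1 or 2", call. = FALSE))
  if (side_specific && length(trend_terms))
    trend_terms <- c(trend_terms, paste0(trend_terms, ":treated"))
  rhs <- c(trend_terms, extras, "strata(treated)")
  resp <- if (episodes) "survival::Surv(t_start, t_stop, event)"
          else "survival::Surv(t, event)"
  form <- stats::as.formula(paste(resp, "~", paste(rhs, collapse = " + ")))

  fit <- survival::coxph(form, data = as.data.frame(cohort), ties = ties,
                         cluster = if (cluster) cohort$mother_id else NULL,
                         x = TRUE, model = FALSE, y = TRUE)
  if (!is.null(fit$fail)) stop("hazard model failed: ", fit$fail, call. = FALSE)
  has_cov <- length(stats::coef(fit)) > 0
  if (has_cov && any(!is.finite(stats::coef(fit))))
    stop("hazard model did not converge (non-finite coefficients)",
         call. = FALSE)

  risk_score <- if (has_cov) exp(as.vector(fit$x %*% stats::coef(fit)))
                else rep(1, nrow(cohort))
  base <- breslow_baseline(
    t_start = if (episodes) cohort$t_start else rep(0, nrow(cohort)),
    t_stop = if (episodes) cohort$t_stop else cohort$t,
    event = cohort$event, stratum = cohort$treated, risk_score = risk_score,
    X = if (has_cov) fit$x else NULL)

  cf <- if (has_cov) stats::coef(fit) else numeric(0)
  nm <- names(cf)
  named <- function(V) {
    if (is.null(V)) V <- matrix(0, length(cf), length(cf))
    dimnames(V) <- list(nm, nm)
    V
  }
  structure(list(
    coefficients = cf,
    vcov = if (has_cov) named(fit$var) else matrix(0, 0, 0),
    naive_vcov = if (has_cov) named(fit$naive.var) else matrix(0, 0, 0),
    baseline = base,
    max_time = max(if (episodes) cohort$t_stop else cohort$t),
    n = nrow(cohort), nevent = sum(cohort$event),
    nclusters = length(unique(cohort$mother_id)),
    trend_order = trend_order, extras = extras,
    side_specific = side_specific, ties = ties, clustered = cluster,
    episodes = episodes,
    coxph = fit
  ), class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf(
    "Stratified hazard model: %d rows, %d events, %d mother clusters\n",
    x$n, x$nevent, x$nclusters))
  if (length(x$coefficients)) {
    se <- sqrt(diag(x$vcov))
    tab <- data.frame(coef = x$coefficients, `robust se` = se,
                      z = x$coefficients / se, check.names = FALSE)
    print(round(tab, 4))
  } else cat("  (no covariates: stratified null model)\n")
  invisible(x)
}

## Breslow baseline cumulative-hazard increments per stratum, with
## Poisson-type increment variances d_k / S0(t_k)^2 and the risk-set weighted
## covariate means xbar_k = S1(t_k)/S0(t_k) needed to propagate coefficient
## uncertainty into the baseline (dLambda_k(beta) = d_k / S0_k(beta), so to
## first order dLambda moves by exp(-xbar_k' dbeta)).  Handles delayed entry.
breslow_baseline <- function(t_start, t_stop, event, stratum, risk_score,
                             X = NULL) {
  p <- if (is.null(X)) 0L else ncol(X)
  out <- list()
  ## weighted sum over the risk set at each event time via sorted cumsums:
  ## sum(w[start < t]) - sum(w[stop < t])
  risk_sum <- function(w, ts, tp, etimes) {
    os <- order(ts); cs_start <- cumsum(w[os]); sorted_start <- ts[os]
    op <- order(tp); cs_stop <- cumsum(w[op]); sorted_stop <- tp[op]
    entered <- c(0, cs_start)[findInterval(etimes, sorted_start,
                                           left.open = TRUE) + 1]
    exited <- c(0, cs_stop)[findInterval(etimes, sorted_stop,
                                         left.open = TRUE) + 1]
    entered - exited
  }
  for (g in sort(unique(stratum))) {
    sel <- stratum == g
    ts <- t_start[sel]; tp <- t_stop[sel]; ev <- event[sel]; rs <- risk_score[sel]
    etimes <- sort(unique(tp[ev == 1]))
    if (!length(etimes)) {
      out[[as.character(g)]] <- list(time = numeric(0), dLambda = numeric(0),
                                     var_dLambda = numeric(0),
                                     xbar = matrix(0, 0, p))
      next
    }
    d <- as.numeric(table(factor(tp[ev == 1], levels = etimes)))
    S0 <- risk_sum(rs, ts, tp, etimes)
    xbar <- matrix(0, length(etimes), p)
    if (p > 0) {
      Xg <- X[sel, , drop = FALSE]
      for (j in seq_len(p))
        xbar[, j] <- risk_sum(rs * Xg[, j], ts, tp, etimes) / S0
      colnames(xbar) <- colnames(X)
    }
    out[[as.character(g)]] <- list(time = etimes, dLambda = d / S0,
                                   var_dLambda = d / S0^2, xbar = xbar)
  }
  out
}

## Linear-predictor weight applied to baseline increments at event times,
## for prediction at running variable `at_u` with optional time-varying
## extras (extras_profile: function(times) -> matrix/named columns).
increment_weights <- function(fit, times, at_u, extras_values = NULL,
                              beta = fit$coefficients, stratum = NULL) {
  if (!length(beta)) return(rep(1, length(times)))
  lp <- numeric(length(times))
  nm <- names(beta)
  add <- function(term, value) {
    if (term %in% nm) lp <<- lp + beta[[term]] * value
  }
  add("u", at_u); add("I(u^2)", at_u^2)
  if (!is.null(stratum)) {
    tr <- as.numeric(stratum)
    add("u:treated", at_u * tr); add("treated:u", at_u * tr)
    add("I(u^2):treated", at_u^2 * tr); add("treated:I(u^2)", at_u^2 * tr)
  }
  if (!is.null(extras_values)) {
    for (e in colnames(extras_values)) add(e, extras_values[, e])
  }
  exp(lp)
}

resolve_extras_profile <- function(fit, times, extras_profile) {
  if (!length(fit$extras)) return(NULL)
  if (is.null(extras_profile)) {
    matrix(0, length(times), length(fit$extras),
           dimnames = list(NULL, fit$extras))
  } else {
    vals <- extras_profile(times)
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = 1,
                                           dimnames = list(NULL, fit$extras))
    vals
  }
}

#' Predict cumulative incidence at the cut-off
#'
#' \eqn{F_g(t \mid u) = 1 - \exp\{-\Lambda_{g0}(t)\, e^{\beta' x(u)}\}} per
#' stratum, evaluated at `at_u = 0` by default — i.e. at the cut-off,
#' removing the cohort trend so the two strata are directly comparable.
#'
#' @param fit A `survival_fit`.
#' @param at_u Running-variable value at which to predict (default 0).
#' @param times Evaluation grid; defaults to all baseline event times.
#' @param extras_profile Optional function mapping follow-up times to values
#'   of the extra covariates (e.g. the ICD-era indicator as a function of
#'   follow-up time for a birth at the cut-off); defaults to zero.
#' @return Data.frame with columns `time`, `stratum` (`"control"` /
#'   `"treated"`), `cuminc`.
#' @export
predict_cumulative_incidence <- function(fit, at_u = 0, times = NULL,
                                         extras_profile = NULL) {
  out <- list()
  for (g in names(fit$baseline)) {
    b <- fit$baseline[[g]]
    ev <- resolve_extras_profile(fit, b$time, extras_profile)
    w <- increment_weights(fit, b$time, at_u, ev, stratum = as.numeric(g))
    Lambda <- cumsum(b$dLambda * w)
    tt <- if (is.null(times)) b$time else times
    idx <- findInterval(tt, b$time)
    L <- c(0, Lambda)[idx + 1]
    out[[g]] <- data.frame(
      time = tt,
      stratum = ifelse(as.numeric(g) == 1, "treated", "control"),
      cuminc = -expm1(-L))
  }
  do.call(rbind, out)
}

#' Horizon-specific risk differences with simulation-based intervals
#'
#' Point estimate per horizon `h`:
#' \eqn{RD_h = 1000\,[F_{control}(h \mid u=0) - F_{treated}(h \mid u=0)]}
#' (positive = fewer diagnoses among the eligible).  Uncertainty by joint
#' parametric simulation: coefficient draws from the cluster-robust normal
#' approximation, propagated into the Breslow baselines through the risk-set
#' denominators (first order: increment k scales by
#' \eqn{\exp(-\bar x_k' \delta\beta)}), plus independent normal
#' perturbations of the increments (truncated at zero) using their
#' Poisson-type variances; the 2.5% and 97.5% empirical quantiles of the
#' simulated risk differences form the interval.  Deterministic given
#' `seed`.
#'
#' @param fit A `survival_fit`.
#' @param horizons Horizons in years (default 5-year intervals to 30).
#' @param n_sims Number of simulation draws (>= 100; the reference analysis
#'   uses 100 000, desk-scale runs 2 000-10 000).
#' @param seed Integer seed.
#' @param at_u Running-variable value for prediction (default 0, the
#'   cut-off).
#' @param extras_profile See [predict_cumulative_incidence()].
#' @param include_baseline_uncertainty Perturb the baseline increments
#'   (default TRUE); with FALSE only coefficient uncertainty is propagated.
#' @return An object of class `risk_difference_table`: data.frame with
#'   columns `horizon`, `rd_per_1000` (control minus treated),
#'   `rd_treated_minus_control`, `ci_low`, `ci_high`, `cuminc_control`,
#'   `cuminc_treated`; attributes `n_sims`, `seed`, `at_u`, and `draws`
#'   (horizons x draws matrix of simulated `rd_per_1000`).
#' @export
estimate_risk_differences <- function(fit, horizons = seq(5, 30, by = 5),
                                      n_sims = 10000, seed = 1L, at_u = 0,
                                      extras_profile = NULL,
                                      include_baseline_uncertainty = TRUE) {
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  ## the baseline is flat (and valid) between the last event and the end of
  ## follow-up, so horizons are checked against follow-up, not event times
  maxt <- if (!is.null(fit$max_time)) fit$max_time
          else max(unlist(lapply(fit$baseline, function(b)
            if (length(b$time)) max(b$time) else 0)))
  if (any(horizons > maxt + 1e-9))
    stop("horizons beyond the observed follow-up (max ",
         sprintf("%.2f", maxt), " years)", call. = FALSE)
  horizons <- sort(horizons)

  cuminc_at <- function(beta, dL_list) {
    vals <- vapply(c("0", "1"), function(g) {
      b <- fit$baseline[[g]]
      ev <- resolve_extras_profile(fit, b$time, extras_profile)
      w <- increment_weights(fit, b$time, at_u, ev, beta = beta,
                             stratum = as.numeric(g))
      L <- cumsum(dL_list[[g]] * w)
      -expm1(-c(0, L)[findInterval(horizons, b$time) + 1])
    }, numeric(length(horizons)))
    matrix(vals, nrow = length(horizons), ncol = 2,
           dimnames = list(NULL, c("0", "1")))
  }

  dL_hat <- lapply(fit$baseline, function(b) b$dLambda)
  Fhat <- cuminc_at(fit$coefficients, dL_hat)
  rd_hat <- 1000 * (Fhat[, "0"] - Fhat[, "1"])

  p <- length(fit$coefficients)
  V_sqrt <- if (p) {
    ed <- eigen(fit$vcov, symmetric = TRUE)  # handles singular covariances
    ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
  } else NULL
  draws <- matrix(NA_real_, length(horizons), n_sims)
  with_seed(seed, {
    done <- 0L
    while (done < n_sims) {
      m <- min(5000L, n_sims - done)
      betas <- if (p)
        matrix(fit$coefficients, p, m) + V_sqrt %*%
          matrix(stats::rnorm(p * m), p, m)
      else matrix(0, 0, m)
      pert <- lapply(c("0", "1"), function(g) {
        b <- fit$baseline[[g]]
        k <- length(b$dLambda)
        ## baseline increments move with the coefficient draw through the
        ## risk-set denominator: dLambda_k(beta*) ~ dLambda_k exp(-xbar_k'db)
        adj <- if (p && !is.null(b$xbar) && k > 0)
          exp(-(b$xbar %*% (betas - fit$coefficients)))
        else matrix(1, k, m)
        if (!include_baseline_uncertainty || k == 0)
          matrix(b$dLambda, k, m) * adj
        else pmax(adj * (matrix(b$dLambda, k, m) +
                           matrix(stats::rnorm(k * m, 0,
                                               rep(sqrt(b$var_dLambda), m)),
                                  k, m)), 0)
      })
      names(pert) <- c("0", "1")
      for (s in seq_len(m)) {
        Fs <- cuminc_at(if (p) betas[, s] else numeric(0),
                        list("0" = pert[["0"]][, s], "1" = pert[["1"]][, s]))
        draws[, done + s] <- 1000 * (Fs[, "0"] - Fs[, "1"])
      }
      done <- done + m
    }
  })
  qs <- apply(draws, 1, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(horizon = horizons,
                    rd_per_1000 = rd_hat,
                    rd_treated_minus_control = -rd_hat,
                    ci_low = qs[1, ], ci_high = qs[2, ],
                    cuminc_control = Fhat[, "0"],
                    cuminc_treated = Fhat[, "1"])
  structure(out, class = c("risk_difference_table", "data.frame"),
            n_sims = n_sims, seed = seed, at_u = at_u, draws = draws)
}

#' @export
print.risk_difference_table <- function(x, ...) {
  cat(sprintf(
    "Adjusted risk differences per 1000 women (control - treated; %d sims)\n",
    attr(x, "n_sims")))
  df <- as.data.frame(x)
  df$label <- sprintf("%.1f %s (95%% sim. interval %.1f to %.1f)",
                      abs(df$rd_per_1000),
                      ifelse(df$rd_per_1000 >= 0, "fewer", "more"),
                      df$ci_low, df$ci_high)
  print(df[, c("horizon", "rd_per_1000", "ci_low", "ci_high", "label")],
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Unadjusted cumulative-incidence (1 - Kaplan-Meier) curves by reform group
#'
#' Product-limit estimates per stratum with Greenwood pointwise confidence
#' intervals, returned on the cumulative-incidence scale.
#'
#' @param cohort An `analysis_cohort`.
#' @param conf_type Confidence-interval transformation passed to
#'   [survival::survfit()] (default `"log"`).
#' @return Data.frame with `time`, `stratum`, `cuminc`, `ci_low`, `ci_high`,
#'   `n_risk`, `n_event`.
#' @export
km_curves <- function(cohort, conf_type = "log") {
  sf <- survival::survfit(survival::Surv(t, event) ~ treated,
                          data = as.data.frame(cohort),
                          conf.type = conf_type)
  ss <- summary(sf)
  grp <- ifelse(grepl("=1", as.character(ss$strata)), "treated", "control")
  data.frame(time = ss$time, stratum = grp,
             cuminc = 1 - ss$surv,
             ci_low = 1 - ss$upper, ci_high = 1 - ss$lower,
             n_risk = ss$n.risk, n_event = ss$n.event)
}

#' Cumulative incidence at a horizon from a 1 - KM curve
#'
#' @param km Output of [km_curves()].
#' @param horizon Horizon in years.
#' @param stratum `"control"` or `"treated"`.
#' @return The cumulative incidence (probability scale) at the horizon.
#' @export
km_cuminc_at <- function(km, horizon, stratum) {
  cc <- km[km$stratum == stratum, , drop = FALSE]
  cc <- cc[order(cc$time), , drop = FALSE]
  i <- findInterval(horizon, cc$time)
  if (i == 0) 0 else cc$cuminc[i]
}

#' Mother-level cluster bootstrap for risk differences
#'
#' Cross-check for the parametric simulation interval: resamples mothers
#' with replacement, refits the stratified hazard model, and returns the
#' bootstrap distribution of the horizon risk differences.
#'
#' @param cohort An `analysis_cohort`.
#' @param horizons Horizons in years.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param ... Passed to [fit_hazard_model()].
#' @return List with `rd` (point estimates), `boot` (B x horizons matrix),
#'   `ci_low`, `ci_high` (percentile intervals per 1000).
#' @export
rd_cluster_bootstrap <- function(cohort, horizons = seq(5, 30, by = 5),
                                 B = 200, seed = 1L, ...) {
  fit0 <- fit_hazard_model(cohort, ...)
  rd0 <- estimate_risk_differences(fit0, horizons, n_sims = 100,
                                   seed = seed)$rd_per_1000
  mothers <- unique(cohort$mother_id)
  rows_by_mother <- split(seq_len(nrow(cohort)), cohort$mother_id)
  boot <- with_seed(seed, {
    t(vapply(seq_len(B), function(b) {
      pick <- sample(length(mothers), replace = TRUE)
      idx <- unlist(rows_by_mother[pick], use.names = FALSE)
      dat <- cohort[idx, , drop = FALSE]
      dat$mother_id <- rep(seq_along(pick),
                           lengths(rows_by_mother[pick]))
      class(dat) <- c("analysis_cohort", "data.frame")
      f <- fit_hazard_model(dat, ...)
      F0 <- predict_cumulative_incidence(f, at_u = 0)
      vapply(horizons, function(h) {
        1000 * (cuminc_from_curve(F0, h, "control") -
                  cuminc_from_curve(F0, h, "treated"))
      }, numeric(1))
    }, numeric(length(horizons))))
  })
  list(rd = rd0, boot = boot,
       ci_low = apply(boot, 2, stats::quantile, 0.025),
       ci_high = apply(boot, 2, stats::quantile, 0.975))
}

cuminc_from_curve <- function(curve, horizon, stratum) {
  cc <- curve[curve$stratum == stratum, , drop = FALSE]
  cc <- cc[order(cc$time), , drop = FALSE]
  i <- findInterval(horizon, cc$time)
  if (i == 0) 0 else cc$cuminc[i]
}
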