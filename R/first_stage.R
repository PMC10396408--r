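first_stage_window <- function(cohort,
                               window = c("1984-02-01", "1984-05-31")) {
  ws <- as_date_strict(window[1]); we <- as_date_strict(window[2])
  keep <- cohort$birth_date >= ws & cohort$birth_date <= we
  out <- cohort[keep, , drop = FALSE]
  attr(out, "fs_window") <- c(ws, we)
  out
}

#' Estimate the discontinuity in leave duration at the cut-off
#'
#' Least-squares fit of `leave_days` on the treatment indicator with
#' side-specific polynomial trends in the running variable
#' (`treated + u + treated:u` at the default order 1).  The jump is the
#' treated coefficient; standard errors are cluster-robust by mother
#' (`sandwich::vcovCL`), reducing to heteroskedasticity-robust when every
#' mother appears once.  Leave must be observed for all rows, so the window
#' should lie in 1984 or later (registry leave data start January 1984).
#'
#' @param cohort An `analysis_cohort` (or any data.frame with `leave_days`,
#'   `leave_observed`, `u`, `treated`, `mother_id`).
#' @param window Calendar window of births used; default 1 Feb-31 May 1984.
#' @param trend_order 0 (difference in side means), 1 (side-specific linear,
#'   default) or 2 (side-specific quadratic).
#' @param cluster Cluster the standard errors by mother (default TRUE).
#' @return An object of class `first_stage_result`: list with `estimate`
#'   (days), `se`, `ci` (95%), `p_value`, `trend_order`, `window`,
#'   `slopes` (per-side trend coefficients), `n`, `n_clusters`, `fit`.
#' @export
estimate_leave_jump <- function(cohort,
                                window = c("1984-02-01", "1984-05-31"),
                                trend_order = 1, cluster = TRUE) {
  dat <- first_stage_window(cohort, window)
  if (any(!dat$leave_observed))
    stop("leave duration unobserved for some births in the window; ",
         "restrict the window to 1984 onwards", call. = FALSE)
  if (!any(dat$treated == 1) || !any(dat$treated == 0))
    stop("first-stage window must contain births on both sides of the cut-off",
         call. = FALSE)
  for (side in split(dat$u, dat$treated))
    if (trend_order >= 1 && length(unique(side)) < trend_order + 1)
      stop("too few distinct running-variable values on one side for the ",
           "requested trend order", call. = FALSE)

  form <- switch(as.character(trend_order),
                 "0" = leave_days ~ treated,
                 "1" = leave_days ~ treated + u + treated:u,
                 "2" = leave_days ~ treated + u + treated:u +
                   I(u^2) + treated:I(u^2),
                 stop("trend_order must be 0, 1 or 2", call. = FALSE))
  fit <- stats::lm(form, data = dat)
  V <- if (cluster) sandwich::vcovCL(fit, cluster = dat$mother_id, type = "HC1")
       else sandwich::vcovHC(fit, type = "HC1")
  est <- unname(stats::coef(fit)["treated"])
  se <- sqrt(V["treated", "treated"])
  z <- if (se > 0) est / se else Inf * sign(est)
  slopes <- stats::coef(fit)[grep("^u$|:u$|u\\^2", names(stats::coef(fit)))]
  structure(list(
    estimate = est, se = se,
    ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
    p_value = 2 * stats::pnorm(-abs(z)),
    trend_order = trend_order,
    window = attr(dat, "fs_window"),
    slopes = slopes,
    n = nrow(dat),
    n_clusters = length(unique(dat$mother_id)),
    fit = fit
  ), class = "first_stage_result")
}

#' @export
print.first_stage_result <- function(x, ...) {
  cat(sprintf(
    "First stage: jump at cut-off %.2f days (cluster-robust SE %.2f)\n",
    x$estimate, x$se))
  cat(sprintf("  95%% CI %.2f to %.2f, p = %.2g; trend order %d; %d births, %d mothers\n",
              x$ci[1], x$ci[2], x$p_value, x$trend_order, x$n, x$n_clusters))
  invisible(x)
}

#' Daily mean leave series
#'
#' One row per calendar day with at least one birth with observed leave:
#' the day, the mean leave days, and the number of births.  This is the
#' tabular analogue of the dot-per-day first-stage figure.
#'
#' @inheritParams estimate_leave_jump
#' @return Data.frame with columns `date`, `mean_leave_days`, `n`.
#' @export
daily_mean_series <- function(cohort, window = c("1984-02-01", "1984-05-31")) {
  dat <- first_stage_window(cohort, window)
  dat <- dat[dat$leave_observed & !is.na(dat$leave_days), , drop = FALSE]
  if (!nrow(dat))
    return(data.frame(date = as.Date(character()), mean_leave_days = numeric(),
                      n = integer()))
  agg <- stats::aggregate(dat$leave_days, by = list(date = dat$birth_date),
                          FUN = mean)
  cnt <- as.data.frame(table(dat$birth_date), stringsAsFactors = FALSE)
  out <- data.frame(date = agg$date, mean_leave_days = agg$x,
                    n = cnt$Freq[match(format(agg$date), cnt$Var1)])
  out[order(out$date), , drop = FALSE]
}

#' Summarise take-up of the additional leave
#'
#' Estimates the share of post-cut-off births that took up the additional
#' entitlement.  Two estimators are reported: `share` (primary), the mixing
#' proportion of the taker component in a constrained Gaussian mixture
#' fitted to post-cut-off leave residuals — the non-taker component is
#' anchored at the pre-cut-off predicted level and the noise SD fixed from
#' the pre-side residual spread, deconvolving day-level noise from the
#' entitlement step — and `share_threshold`, the share of post-cut-off
#' births whose leave exceeds the pre-cut-off predicted level by `margin`
#' (undercounts when noise is comparable to the entitlement).  With `by`,
#' the cut-off jump is re-estimated per level of a factor.
#'
#' @inheritParams estimate_leave_jump
#' @param by Optional name of a factor column; per-level jump estimates are
#'   returned.
#' @param margin Threshold margin in days (default half the 42-day
#'   entitlement extension).
#' @return List with `share`, `share_threshold`, `n_post`, `margin`, and
#'   (with `by`) `by_level`: a data.frame of per-level jumps with CIs.
#' @export
takeup_summary <- function(cohort, window = c("1984-02-01", "1984-05-31"),
                           by = NULL, margin = 21) {
  dat <- first_stage_window(cohort, window)
  dat <- dat[dat$leave_observed & !is.na(dat$leave_days), , drop = FALSE]
  post <- dat[dat$treated == 1, , drop = FALSE]
  if (!nrow(post)) stop("no post-cut-off births in the window", call. = FALSE)

  pre <- dat[dat$treated == 0, , drop = FALSE]
  predicted <- if (nrow(pre) >= 2 && length(unique(pre$u)) >= 2) {
    prefit <- stats::lm(leave_days ~ u, data = pre)
    unname(stats::predict(prefit, newdata = post))
  } else rep(mean(pre$leave_days), nrow(post))
  share_threshold <- mean(post$leave_days > predicted + margin)

  resid <- post$leave_days - predicted
  noise_sd <- if (nrow(pre) >= 30)
    stats::sd(stats::resid(stats::lm(leave_days ~ u, data = pre)))
  else NULL
  share <- takeup_mixture_share(resid, noise_sd = noise_sd,
                                fallback = share_threshold)

  out <- list(share = share, share_threshold = share_threshold,
              n_post = nrow(post), margin = margin)
  if (!is.null(by)) {
    levs <- unique(as.character(dat[[by]]))
    levs <- levs[!is.na(levs)]
    rows <- lapply(levs, function(l) {
      sub <- dat[as.character(dat[[by]]) == l, , drop = FALSE]
      fs <- tryCatch(estimate_leave_jump(sub, window = window),
                     error = function(e) NULL)
      if (is.null(fs)) return(NULL)
      data.frame(level = l, jump = fs$estimate, se = fs$se,
                 ci_low = fs$ci[1], ci_high = fs$ci[2], n = fs$n,
                 stringsAsFactors = FALSE)
    })
    out$by_level <- do.call(rbind, rows)
  }
  out
}

## Take-up share by constrained Gaussian-mixture deconvolution of the
## post-cut-off leave residuals: non-takers sit at the pre-cut-off predicted
## level (component mean fixed at 0), takers at an unknown mean shift; the
## common noise SD is fixed from the pre-side residuals when available,
## otherwise estimated within the EM.  The fixed zero mean removes the flat
## likelihood ridge that makes the unconstrained two-component mixture
## ill-determined when day-level noise is comparable to the entitlement.
takeup_mixture_share <- function(resid, noise_sd = NULL, fallback = NA_real_,
                                 max_iter = 5000, tol = 1e-10) {
  x <- resid[is.finite(resid)]
  if (length(x) < 50 || stats::sd(x) == 0) return(fallback)
  fix_sd <- !is.null(noise_sd) && is.finite(noise_sd) && noise_sd > 0
  p <- mean(x > stats::median(x) + 1); if (p < 0.05 || p > 0.95) p <- 0.5
  mu <- max(mean(x) / max(p, 0.1), 1)
  s2 <- if (fix_sd) noise_sd^2 else {
    v <- stats::var(x) - p * (1 - p) * mu^2
    if (v > 0) v else stats::var(x) / 4
  }
  ll0 <- -Inf
  for (i in seq_len(max_iter)) {
    d1 <- p * stats::dnorm(x, mu, sqrt(s2))
    d0 <- (1 - p) * stats::dnorm(x, 0, sqrt(s2))
    tot <- d1 + d0
    if (any(tot == 0)) return(fallback)
    w <- d1 / tot
    p <- mean(w)
    mu <- sum(w * x) / max(sum(w), .Machine$double.eps)
    if (!fix_sd)
      s2 <- (sum((1 - w) * x^2) + sum(w * (x - mu)^2)) / length(x)
    ll <- sum(log(tot))
    if (ll - ll0 < tol) break
    ll0 <- ll
  }
  if (!is.finite(p) || mu <= 0) return(fallback)
  p
}

#' Manipulation (density) test of the running variable
#'
#' Bins daily birth counts (default 7-day bins, absorbing day-of-week
#' patterns) and fits a Poisson log-linear model of the counts on
#' side-specific linear trends in the bin midpoint plus a level jump at the
#' cut-off.  A significant jump indicates sorting of births around the
#' threshold; the study design expects none.
#'
#' @param registry Data.frame with `birth_date`.
#' @param cutoff Cut-off date.
#' @param window Calendar window of births used (default the full study
#'   window).
#' @param bin_width_days Bin width in days.
#' @return An object of class `density_test_result`: `estimate` (log-rate
#'   jump at the cut-off), `se`, `p_value`, and `bins` (midpoint date, count).
#' @export
density_test <- function(registry, cutoff = derive_cutoff("1984-07-01", 14),
                         window = c("1981-01-01", "1987-12-31"),
                         bin_width_days = 7) {
  cutoff <- as_date_strict(cutoff)
  ws <- as_date_strict(window[1]); we <- as_date_strict(window[2])
  bd <- registry$birth_date
  bd <- bd[!is.na(bd) & bd >= ws & bd <= we]
  ## bins aligned so that a bin edge falls exactly on the cut-off
  lo <- as.numeric(ws - cutoff); hi <- as.numeric(we - cutoff) + 1
  edges <- seq(floor(lo / bin_width_days), ceiling(hi / bin_width_days)) *
    bin_width_days
  x <- as.numeric(bd - cutoff)
  counts <- table(cut(x, edges, right = FALSE))
  mid <- (edges[-length(edges)] + edges[-1] - 1) / 2
  bins <- data.frame(mid_days = mid, count = as.integer(counts),
                     post = as.integer(mid >= 0))
  if (sum(bins$post == 1) < 2 || sum(bins$post == 0) < 2)
    stop("need at least 2 bins on each side of the cut-off", call. = FALSE)
  if (all(bins$count[bins$post == 1] == 0) || all(bins$count[bins$post == 0] == 0))
    stop("no births on one side of the cut-off", call. = FALSE)
  fit <- stats::glm(count ~ post + mid_days + post:mid_days,
                    family = stats::poisson(), data = bins)
  sm <- summary(fit)$coefficients
  structure(list(estimate = sm["post", "Estimate"],
                 se = sm["post", "Std. Error"],
                 p_value = sm["post", "Pr(>|z|)"],
                 bin_width_days = bin_width_days,
                 bins = bins, fit = fit),
            class = "density_test_result")
}

#' @export
print.density_test_result <- function(x, ...) {
  cat(sprintf(
    "Density test: log-rate jump at cut-off %.4f (SE %.4f), p = %.3f\n",
    x$estimate, x$se, x$p_value))
  cat(sprintf("  %d bins of %d days\n", nrow(x$bins), x$bin_width_days))
  invisible(x)
}
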