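#' Parameters for the synthetic birth-registry generator
#'
#' Defaults emulate the Danish 1981-1987 birth cohort around the 1984
#' parental-leave extension: daily births over 1981-01-01 to 1987-12-31,
#' covariate prevalences from the registry population description, a
#' discontinuity in leave duration at the eligibility cut-off with imperfect
#' take-up, piecewise-exponential time to first inpatient psychiatric
#' diagnosis with stratum-specific planted incidence profiles, and censoring
#' by death, emigration and the administrative cut-off 2017-12-31.
#'
#' @param birth_window_start,birth_window_end Calendar window of births.
#' @param mean_births_per_day Expected births per calendar day (paper-scale
#'   default 145, about 371k births over the 7-year window).
#' @param covariate_prevalences Named list of marginal prevalences; see
#'   Defaults.  Three-level education shares (plus a missing share) must each
#'   sum to 1.
#' @param leave_params Named list: `baseline_days` (pre-reform mean leave),
#'   `pre_trend`/`post_trend` (days per year of running variable),
#'   `entitlement_extra_days` (mean additional days among takers),
#'   `takeup_probability`, `noise_sd` (Gaussian day noise, truncated at 0),
#'   `leave_observed_from` (leave is recorded only for births on/after this
#'   date), and optional `overrides`: a named list, one element per covariate,
#'   each a named list of per-level `takeup`/`extra_days` overrides, e.g.
#'   `list(partnered = list("FALSE" = list(takeup = 0.4, extra_days = 30)))`.
#' @param hazard_params Named list: `breaks` and `control_rates`
#'   (piecewise-constant control hazard, events per person-year),
#'   `treated_rates` (planted eligible-stratum rates; overrides
#'   `treatment_log_hr` when non-NULL), `treatment_log_hr` (scalar log hazard
#'   ratio applied to control rates when `treated_rates` is NULL),
#'   `subgroup_treatment_log_hr` (named list: covariate -> named vector of
#'   additional treated-only log-HRs per level), `covariate_log_hr` (named
#'   vector of prognostic log-HRs applied to everyone), `mother_frailty_sd`
#'   (SD of a mother-level log-normal frailty; 0 disables),
#'   `emigration_rate`, `death_rate` (exponential censoring, per person-year),
#'   `admin_censor_date`.
#' @param births_per_mother Named numeric vector of probabilities for the
#'   number of in-window births per mother (names "1", "2", ...).
#' @param missing_birth_date_share Share of births whose birth date is blanked
#'   (to exercise exclusion logging); default 0.
#' @param seed Default seed used when `generate_registry` is called without one.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(
    birth_window_start = "1981-01-01",
    birth_window_end = "1987-12-31",
    mean_births_per_day = 145,
    covariate_prevalences = list(),
    leave_params = list(),
    hazard_params = list(),
    births_per_mother = c("1" = 0.75, "2" = 0.23, "3" = 0.02),
    missing_birth_date_share = 0,
    seed = 1L) {

  prof <- default_incidence_profile()
  prev <- utils::modifyList(list(
    partnered = 0.846,
    family_education = c(low = 0.214, intermediate = 0.472, high = 0.299,
                         missing = 0.015),
    mother_education = c(low = 0.408, intermediate = 0.331, high = 0.221,
                         missing = 0.040),
    below_mean_income = 0.452,
    low_birthweight = 0.05,
    birthweight_missing = 0.011,
    singleton = 0.989,
    prior_diagnosis = 0.003
  ), covariate_prevalences)

  lv <- utils::modifyList(list(
    baseline_days = 98,
    pre_trend = 0,
    post_trend = 0,
    entitlement_extra_days = 32.85 / 0.822,
    takeup_probability = 0.822,
    noise_sd = 20,
    leave_observed_from = "1984-01-01",
    overrides = list()
  ), leave_params)

  hz <- utils::modifyList(list(
    breaks = prof$breaks,
    control_rates = prof$control_rates,
    treated_rates = prof$treated_rates,
    treatment_log_hr = 0,
    subgroup_treatment_log_hr = list(),
    covariate_log_hr = c(),
    mother_frailty_sd = 0,
    emigration_rate = 0.00176,
    death_rate = 0.00138,
    admin_censor_date = "2017-12-31"
  ), hazard_params)

  p <- list(
    birth_window_start = as_date_strict(birth_window_start),
    birth_window_end = as_date_strict(birth_window_end),
    mean_births_per_day = mean_births_per_day,
    covariate_prevalences = prev,
    leave_params = lv,
    hazard_params = hz,
    births_per_mother = births_per_mother,
    missing_birth_date_share = missing_birth_date_share,
    seed = as.integer(seed)
  )
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  if (p$birth_window_start >= p$birth_window_end)
    stop("birth_window_start must precede birth_window_end", call. = FALSE)
  check_nonneg(p$mean_births_per_day, "mean_births_per_day")
  prev <- p$covariate_prevalences
  check_prob(prev$partnered, "partnered")
  check_prob(prev$below_mean_income, "below_mean_income")
  check_prob(prev$low_birthweight, "low_birthweight")
  check_prob(prev$singleton, "singleton")
  check_prob(prev$prior_diagnosis, "prior_diagnosis")
  check_shares(prev$family_education, "family_education")
  check_shares(prev$mother_education, "mother_education")
  check_prob(p$leave_params$takeup_probability, "takeup_probability")
  check_nonneg(p$leave_params$noise_sd, "noise_sd")
  hz <- p$hazard_params
  check_nonneg(hz$control_rates, "control_rates")
  if (!is.null(hz$treated_rates)) check_nonneg(hz$treated_rates, "treated_rates")
  check_nonneg(hz$emigration_rate, "emigration_rate")
  check_nonneg(hz$death_rate, "death_rate")
  check_shares(p$births_per_mother, "births_per_mother")
  check_prob(p$missing_birth_date_share, "missing_birth_date_share")
  invisible(p)
}

draw_level <- function(n, shares) {
  factor(sample(names(shares), n, replace = TRUE, prob = shares),
         levels = names(shares))
}

#' Generate a synthetic birth registry
#'
#' Draws a Poisson number of births over the window (uniform across days),
#' allocates them to mothers according to `births_per_mother` (mother-level
#' covariates are shared across a mother's births), then fills leave days via
#' [assign_leave_days()] and outcome/censoring dates via
#' [simulate_event_times()].  Deterministic given `seed`.
#'
#' @param params A [generator_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @param cutoff Eligibility cut-off date; defaults to the 1984 reform's.
#' @return A data.frame of birth records; one row per birth with columns
#'   `mother_id`, `child_id`, `birth_date`, `leave_days`, `leave_observed`,
#'   `birthweight_class`, `singleton`, `partnered`, `family_education`,
#'   `mother_education`, `below_mean_income`, `prior_diagnosis`,
#'   `event_date`, `censor_date`, `censor_reason`.
#' @export
generate_registry <- function(params, seed = params$seed,
                              cutoff = derive_cutoff("1984-07-01", 14)) {
  validate_generator_params(params)
  with_seed(seed, {
    days <- seq(params$birth_window_start, params$birth_window_end, by = "day")
    n_births <- stats::rpois(1, params$mean_births_per_day * length(days))
    if (n_births == 0) return(empty_registry())

    ## allocate births to mothers
    sizes <- as.integer(names(params$births_per_mother))
    mean_size <- sum(sizes * params$births_per_mother)
    n_draw <- ceiling(n_births / mean_size * 1.2) + 10L
    msize <- sample(sizes, n_draw, replace = TRUE, prob = params$births_per_mother)
    while (sum(msize) < n_births)
      msize <- c(msize, sample(sizes, 100L, replace = TRUE,
                               prob = params$births_per_mother))
    keep <- which(cumsum(msize) >= n_births)[1]
    msize <- msize[seq_len(keep)]
    msize[keep] <- msize[keep] - (sum(msize) - n_births)
    mother_id <- rep(seq_along(msize), msize)

    prev <- params$covariate_prevalences
    n_m <- length(msize)
    ## mother-level covariates, carried to each of her births
    m_partnered <- stats::runif(n_m) < prev$partnered
    m_fam_edu <- draw_level(n_m, prev$family_education)
    m_mom_edu <- draw_level(n_m, prev$mother_education)
    m_income <- stats::runif(n_m) < prev$below_mean_income

    bw <- ifelse(stats::runif(n_births) < prev$birthweight_missing, "missing",
                 ifelse(stats::runif(n_births) < prev$low_birthweight /
                          (1 - prev$birthweight_missing), "low", "normal"))
    reg <- data.frame(
      mother_id = mother_id,
      child_id = seq_len(n_births),
      birth_date = params$birth_window_start +
        sample.int(length(days), n_births, replace = TRUE) - 1L,
      leave_days = NA_real_,
      leave_observed = FALSE,
      birthweight_class = factor(bw, levels = c("low", "normal", "missing")),
      singleton = stats::runif(n_births) < prev$singleton,
      partnered = m_partnered[mother_id],
      family_education = m_fam_edu[mother_id],
      mother_education = m_mom_edu[mother_id],
      below_mean_income = m_income[mother_id],
      prior_diagnosis = stats::runif(n_births) < prev$prior_diagnosis,
      stringsAsFactors = FALSE
    )
    if (params$missing_birth_date_share > 0) {
      blank <- stats::runif(n_births) < params$missing_birth_date_share
      reg$birth_date[blank] <- as.Date(NA)
    }
    reg <- assign_leave_days(reg, params$leave_params, cutoff,
                             seed = derive_seed(seed, 1L))
    reg <- simulate_event_times(reg, params$hazard_params, cutoff,
                                seed = derive_seed(seed, 2L))
    reg
  })
}

empty_registry <- function() {
  data.frame(mother_id = integer(), child_id = integer(),
             birth_date = as.Date(character()), leave_days = numeric(),
             leave_observed = logical(),
             birthweight_class = factor(character(),
                                        levels = c("low", "normal", "missing")),
             singleton = logical(), partnered = logical(),
             family_education = factor(character(),
                                       levels = c("low", "intermediate", "high",
                                                  "missing")),
             mother_education = factor(character(),
                                       levels = c("low", "intermediate", "high",
                                                  "missing")),
             below_mean_income = logical(), prior_diagnosis = logical(),
             event_date = as.Date(character()),
             censor_date = as.Date(character()),
             censor_reason = character(), stringsAsFactors = FALSE)
}

#' Assign leave days around the eligibility cut-off
#'
#' Leave is `baseline + side-specific linear trend in the running variable +
#' truncated Gaussian noise`; births on or after the cut-off additionally
#' receive `entitlement_extra_days` with probability `takeup_probability`
#' (per-subgroup overrides honoured), so the expected discontinuity at the
#' cut-off is `takeup_probability * entitlement_extra_days`.  Leave is flagged
#' unobserved for births before `leave_observed_from` (registry leave data
#' start in January 1984).
#'
#' @param registry Data.frame with at least `birth_date` and any override
#'   covariates.
#' @param leave_params See [generator_params()].
#' @param cutoff Eligibility cut-off date.
#' @param seed Integer seed.
#' @return `registry` with `leave_days` and `leave_observed` filled.
#' @export
assign_leave_days <- function(registry, leave_params, cutoff, seed = 1L) {
  lv <- leave_params
  check_prob(lv$takeup_probability, "takeup_probability")
  with_seed(seed, {
    n <- nrow(registry)
    if (n == 0) return(registry)
    u <- years_between(cutoff, registry$birth_date)
    post <- !is.na(u) & u >= 0
    takeup <- rep(lv$takeup_probability, n)
    extra <- rep(lv$entitlement_extra_days, n)
    for (var in names(lv$overrides)) {
      for (lev in names(lv$overrides[[var]])) {
        ov <- lv$overrides[[var]][[lev]]
        sel <- as.character(registry[[var]]) == lev
        sel[is.na(sel)] <- FALSE
        if (!is.null(ov$takeup)) takeup[sel] <- check_prob(ov$takeup, "takeup")
        if (!is.null(ov$extra_days)) extra[sel] <- ov$extra_days
      }
    }
    leave <- lv$baseline_days +
      ifelse(post, lv$post_trend * u, lv$pre_trend * u) +
      stats::rnorm(n, 0, lv$noise_sd)
    takers <- post & stats::runif(n) < takeup
    leave[takers] <- leave[takers] + extra[takers]
    registry$leave_days <- pmax(leave, 0)
    registry$leave_observed <- !is.na(registry$birth_date) &
      registry$birth_date >= as.Date(lv$leave_observed_from)
    registry$leave_days[!registry$leave_observed] <- NA_real_
    registry
  })
}

#' Simulate outcome and censoring dates
#'
#' Time to first post-birth inpatient psychiatric diagnosis is drawn from a
#' piecewise-exponential model: the control stratum follows `control_rates`,
#' the eligible stratum `treated_rates` (or control rates scaled by
#' `exp(treatment_log_hr)`), both multiplied by `exp()` of any prognostic
#' covariate effects, treated-only subgroup effects, and a mother-level
#' log-normal frailty.  Independent exponential emigration and death times and
#' the administrative cut-off censor follow-up; the event is recorded only if
#' it precedes censoring.
#'
#' @param registry Data.frame of births (needs `birth_date`, `mother_id`, and
#'   any covariates named in the hazard parameters).
#' @param hazard_params See [generator_params()].
#' @param cutoff Eligibility cut-off date (defines the treated stratum).
#' @param seed Integer seed.
#' @return `registry` with `event_date`, `censor_date`, `censor_reason` filled.
#' @export
simulate_event_times <- function(registry, hazard_params, cutoff, seed = 1L) {
  hz <- hazard_params
  stopifnot(as.Date(hz$admin_censor_date) > max(registry$birth_date, na.rm = TRUE))
  with_seed(seed, {
    n <- nrow(registry)
    if (n == 0) return(registry)
    breaks <- hz$breaks
    J <- length(hz$control_rates)
    treated <- !is.na(registry$birth_date) & registry$birth_date >= as.Date(cutoff)

    ## per-interval rate matrix: stratum baseline x individual multiplier
    rate_mat <- matrix(rep(hz$control_rates, each = n), n, J)
    tr_rates <- if (!is.null(hz$treated_rates)) hz$treated_rates
                else hz$control_rates * exp(hz$treatment_log_hr)
    rate_mat[treated, ] <- matrix(rep(tr_rates, each = sum(treated)),
                                  sum(treated), J)
    lp <- numeric(n)
    for (v in names(hz$covariate_log_hr))
      lp <- lp + hz$covariate_log_hr[[v]] *
        as.numeric(as.logical(registry[[v]]))
    for (v in names(hz$subgroup_treatment_log_hr)) {
      eff <- hz$subgroup_treatment_log_hr[[v]]
      lev <- as.character(registry[[v]])
      add <- ifelse(treated & lev %in% names(eff), eff[lev], 0)
      add[is.na(add)] <- 0
      lp <- lp + add
    }
    if (hz$mother_frailty_sd > 0) {
      mid <- match(registry$mother_id, unique(registry$mother_id))
      fr <- stats::rnorm(max(mid), 0, hz$mother_frailty_sd)
      lp <- lp + fr[mid]
    }
    rate_mat <- rate_mat * exp(lp)

    ## invert the individual piecewise cumulative hazard at an Exp(1) draw
    d <- diff(breaks)
    cumH <- rate_mat %*% outer(seq_len(J), seq_len(J),
                               function(k, j) d[k] * (k <= j))
    E <- stats::rexp(n)
    j <- pmin(rowSums(cumH < E) + 1L, J)
    Hprev <- cbind(0, cumH)[cbind(seq_len(n), j)]
    rj <- rate_mat[cbind(seq_len(n), j)]
    t_event <- breaks[j] + ifelse(rj > 0, (E - Hprev) / rj, Inf)

    t_emig <- if (hz$emigration_rate > 0) stats::rexp(n, hz$emigration_rate)
              else rep(Inf, n)
    t_death <- if (hz$death_rate > 0) stats::rexp(n, hz$death_rate)
               else rep(Inf, n)
    t_admin <- years_between(registry$birth_date, as.Date(hz$admin_censor_date))
    t_cens <- pmin(t_emig, t_death, t_admin)
    reason <- ifelse(t_admin <= pmin(t_emig, t_death), "admin",
                     ifelse(t_death <= t_emig, "death", "emigration"))
    has_event <- t_event < t_cens
    ## rows with a missing birth date carry no outcome information
    has_event[is.na(has_event)] <- FALSE
    reason[is.na(t_admin)] <- NA_character_

    day <- function(t) registry$birth_date + pmax(1L, as.integer(round(t * DAYS_PER_YEAR)))
    registry$event_date <- as.Date(ifelse(has_event, day(t_event), NA),
                                   origin = "1970-01-01")
    registry$censor_date <- day(t_cens)
    ## administrative censoring lands exactly on the cut-off date
    admin <- !is.na(reason) & reason == "admin"
    registry$censor_date[admin] <- as.Date(hz$admin_censor_date)
    registry$censor_reason <- ifelse(has_event, NA_character_, reason)
    registry$censor_date[has_event] <- as.Date(NA)
    registry
  })
}
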