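# Independent oracles and small fixture builders used across the suite.

# Breslow partial log-likelihood for a stratified proportional-hazards model,
# computed by direct enumeration of risk sets (O(n^2); fine for toy data).
# Independent of survival::coxph and of the package's fitting path.
brute_partial_loglik <- function(beta, X, t, event, stratum) {
  X <- as.matrix(X)
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (g in unique(stratum)) {
    sg <- which(stratum == g)
    for (tt in unique(t[sg][event[sg] == 1])) {
      dead <- sg[t[sg] == tt & event[sg] == 1]
      risk <- sg[t[sg] >= tt]
      ll <- ll + sum(eta[dead]) - length(dead) * log(sum(exp(eta[risk])))
    }
  }
  ll
}

brute_pl_maximizer <- function(X, t, event, stratum, start = NULL) {
  X <- as.matrix(X)
  if (is.null(start)) start <- rep(0, ncol(X))
  opt <- stats::optim(start, function(b)
    -brute_partial_loglik(b, X, t, event, stratum),
    method = "BFGS", control = list(reltol = 1e-14, maxit = 500))
  opt$par
}

# Nelson-Aalen cumulative hazard by hand: sum of d_i / n_i at event times.
nelson_aalen <- function(t, event) {
  et <- sort(unique(t[event == 1]))
  d <- vapply(et, function(x) sum(t == x & event == 1), numeric(1))
  n <- vapply(et, function(x) sum(t >= x), numeric(1))
  list(time = et, cumhaz = cumsum(d / n), dLambda = d / n)
}

# Minimal analysis-cohort data.frame from raw vectors (bypasses the cohort
# builder so estimator tests control their inputs exactly).
toy_cohort <- function(t, event, treated, u = NULL, mother_id = NULL, ...) {
  n <- length(t)
  dat <- data.frame(
    t = t, event = event, treated = treated,
    u = if (is.null(u)) ifelse(treated == 1, 0.5, -0.5) else u,
    mother_id = if (is.null(mother_id)) seq_len(n) else mother_id,
    child_id = seq_len(n),
    birth_date = as.Date("1984-03-26") +
      round((if (is.null(u)) ifelse(treated == 1, 0.5, -0.5) else u) * 365.25),
    ...)
  structure(dat, class = c("analysis_cohort", "data.frame"),
            reform = reform_spec(),
            window = c(start = as.Date("1981-01-01"),
                       end = as.Date("1987-12-31")),
            admin_censor_date = as.Date("2017-12-31"))
}

# Small registry with hand-set dates for cohort-construction tests.
toy_registry <- function(birth_dates, event_dates = NULL, censor_dates = NULL,
                         mother_id = NULL, leave_days = NULL) {
  n <- length(birth_dates)
  bd <- as.Date(birth_dates)
  ed <- if (is.null(event_dates)) as.Date(rep(NA, n)) else as.Date(event_dates)
  cd <- if (is.null(censor_dates)) as.Date(rep(NA, n)) else as.Date(censor_dates)
  cd[is.na(ed) & is.na(cd)] <- as.Date("2017-12-31")
  data.frame(
    mother_id = if (is.null(mother_id)) seq_len(n) else mother_id,
    child_id = seq_len(n),
    birth_date = bd,
    leave_days = if (is.null(leave_days)) rep(98, n) else leave_days,
    leave_observed = !is.na(bd) & bd >= as.Date("1984-01-01"),
    partnered = rep(TRUE, n),
    event_date = ed,
    censor_date = cd,
    censor_reason = ifelse(is.na(ed), "admin", NA_character_),
    stringsAsFactors = FALSE)
}

# Generator scenario scaled for quick tests.
small_params <- function(..., mean_births_per_day = 4, seed = 1L) {
  generator_params(mean_births_per_day = mean_births_per_day, seed = seed, ...)
}
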