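test_that("stratified null-model baselines equal Nelson-Aalen exactly", {
  coh <- build_cohort(generate_registry(small_params(mean_births_per_day = 2,
                                                     seed = 71)))
  fit <- fit_hazard_model(coh, trend_order = 0)
  for (g in c(0, 1)) {
    sel <- coh$treated == g
    na <- nelson_aalen(coh$t[sel], coh$event[sel])
    b <- fit$baseline[[as.character(g)]]
    expect_equal(b$time, na$time, tolerance = 1e-12)
    expect_equal(cumsum(b$dLambda), na$cumhaz, tolerance = 1e-12)
  }
})

test_that("the partial-likelihood fit matches a brute-force maximizer", {
  set.seed(73)
  n <- 20
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.5 * x))
  event <- as.integer(t < quantile(t, 0.8))
  treated <- rep(c(0L, 1L), each = n / 2)
  dat <- toy_cohort(t = t, event = event, treated = treated)
  dat$x <- x
  fit <- fit_hazard_model(dat, trend_order = 0, extras = "x")
  oracle <- brute_pl_maximizer(matrix(x, ncol = 1), t, event, treated)
  expect_equal(unname(fit$coefficients["x"]), oracle, tolerance = 1e-6)
  # and the score at the maximum is numerically zero
  eps <- 1e-5
  b <- unname(fit$coefficients["x"])
  score <- (brute_partial_loglik(b + eps, matrix(x, ncol = 1), t, event,
                                 treated) -
            brute_partial_loglik(b - eps, matrix(x, ncol = 1), t, event,
                                 treated)) / (2 * eps)
  expect_lt(abs(score), 1e-4)
})

test_that("two-covariate fits also match the brute-force oracle", {
  set.seed(79)
  n <- 24
  u <- runif(n, -2, 2)
  x <- rbinom(n, 1, 0.4)
  t <- rexp(n, 0.1 * exp(0.3 * x - 0.1 * u))
  event <- rep(1L, n)
  treated <- as.integer(u >= 0)
  dat <- toy_cohort(t = t, event = event, treated = treated, u = u)
  dat$x <- x
  fit <- fit_hazard_model(dat, trend_order = 1, extras = "x")
  oracle <- brute_pl_maximizer(cbind(u, x), t, event, treated)
  expect_equal(unname(fit$coefficients[c("u", "x")]), oracle,
               tolerance = 1e-6)
})

test_that("a planted log-hazard ratio is recovered within 3 SEs", {
  set.seed(83)
  n <- 6000
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.05 * exp(0.5 * x))
  cens <- runif(n, 0, 40)
  event <- as.integer(t <= cens)
  dat <- toy_cohort(t = pmin(t, cens), event = event,
                    treated = rbinom(n, 1, 0.5))
  dat$x <- x
  fit <- fit_hazard_model(dat, trend_order = 0, extras = "x")
  se <- sqrt(diag(fit$vcov))["x"]
  expect_lt(abs(fit$coefficients["x"] - 0.5), 3 * se)
})

test_that("singleton clusters make the clustered and robust variances equal", {
  coh <- build_cohort(generate_registry(small_params(mean_births_per_day = 2,
                                                     seed = 89)))
  coh$mother_id <- seq_len(nrow(coh))  # force singletons
  fit <- fit_hazard_model(coh, trend_order = 1)
  oracle <- survival::coxph(survival::Surv(t, event) ~ u + strata(treated),
                            data = as.data.frame(coh), ties = "breslow",
                            robust = TRUE)
  expect_equal(unname(fit$vcov), unname(oracle$var), tolerance = 1e-10)
})

test_that("baseline at the cut-off agrees with survfit prediction", {
  coh <- build_cohort(generate_registry(small_params(mean_births_per_day = 3,
                                                     seed = 97)))
  fit <- fit_hazard_model(coh, trend_order = 2)
  sf <- survival::survfit(fit$coxph, newdata = data.frame(u = 0),
                          stype = 2, ctype = 1)
  pred <- predict_cumulative_incidence(fit, at_u = 0)
  # compare control-stratum cumulative hazard at its event times
  ours <- pred[pred$stratum == "control", ]
  idx <- sf$strata
  sf_time <- sf$time[seq_len(idx[1])]
  sf_surv <- sf$surv[seq_len(idx[1])]
  keep <- sf_time %in% ours$time
  expect_equal(1 - sf_surv[keep], ours$cuminc, tolerance = 1e-8)
})

test_that("1-KM matches the hand-computed product limit", {
  # events at t=1,3; censorings at 2,4:
  # S(1) = 3/4, S(3) = 3/4 * 1/2 -> 1-KM = 0.25 then 0.625
  dat <- toy_cohort(t = c(1, 2, 3, 4), event = c(1L, 0L, 1L, 0L),
                    treated = rep(0L, 4))
  dat2 <- toy_cohort(t = c(1, 2), event = c(0L, 0L), treated = rep(1L, 2))
  km <- km_curves(rbind(dat, dat2))
  ctrl <- km[km$stratum == "control" & km$n_event > 0, ]
  expect_equal(ctrl$cuminc, c(0.25, 0.625), tolerance = 1e-12)
  # no events: curve identically zero
  expect_true(all(km$cuminc[km$stratum == "treated"] == 0))
})

test_that("covariate-free prediction equals 1-KM at all event times", {
  coh <- build_cohort(generate_registry(small_params(mean_births_per_day = 2,
                                                     seed = 101)))
  fit <- fit_hazard_model(coh, trend_order = 0)
  pred <- predict_cumulative_incidence(fit)
  km <- km_curves(coh)
  for (g in c("control", "treated")) {
    pg <- pred[pred$stratum == g, ]
    est_km <- vapply(pg$time, km_cuminc_at, numeric(1), km = km, stratum = g)
    # Breslow exp(-Lambda) vs product-limit: equal to first order; at these
    # risk-set sizes the curves agree closely
    expect_equal(pg$cuminc, est_km, tolerance = 5e-3)
  }
})

test_that("exponential data reproduce the closed-form adjusted curve", {
  lam <- 0.004
  p <- generator_params(mean_births_per_day = 8, seed = 103,
                        hazard_params = list(breaks = c(0, 30),
                                             control_rates = lam,
                                             treated_rates = lam,
                                             emigration_rate = 0,
                                             death_rate = 0))
  coh <- build_cohort(generate_registry(p))
  fit <- fit_hazard_model(coh, trend_order = 2)
  pred <- predict_cumulative_incidence(fit, at_u = 0, times = c(10, 20, 30))
  for (g in c("control", "treated")) {
    est <- pred$cuminc[pred$stratum == g]
    truth <- 1 - exp(-lam * c(10, 20, 30))
    n_g <- sum(coh$treated == (g == "treated"))
    expect_true(all(abs(est - truth) < 3 * sqrt(truth * (1 - truth) / n_g) +
                      0.02 * truth))
  }
})

test_that("risk differences: point estimates are seed-invariant and the
           degenerate-variance interval collapses", {
  coh <- build_cohort(generate_registry(small_params(mean_births_per_day = 2,
                                                     seed = 107)))
  fit <- fit_hazard_model(coh, trend_order = 1)
  rd1 <- estimate_risk_differences(fit, horizons = c(5, 30), n_sims = 300,
                                   seed = 1)
  rd2 <- estimate_risk_differences(fit, horizons = c(5, 30), n_sims = 300,
                                   seed = 2)
  expect_equal(rd1$rd_per_1000, rd2$rd_per_1000, tolerance = 1e-12)
  expect_equal(rd1$rd_treated_minus_control, -rd1$rd_per_1000)
  # same seed: bit-reproducible
  rd1b <- estimate_risk_differences(fit, horizons = c(5, 30), n_sims = 300,
                                    seed = 1)
  expect_identical(rd1, rd1b)
  # degenerate variances: all uncertainty removed -> zero-width interval
  fit0 <- fit
  fit0$vcov <- matrix(0, length(fit$coefficients), length(fit$coefficients))
  for (g in names(fit0$baseline)) fit0$baseline[[g]]$var_dLambda[] <- 0
  rd0 <- estimate_risk_differences(fit0, horizons = 5, n_sims = 200, seed = 3)
  expect_equal(rd0$ci_low, rd0$rd_per_1000, tolerance = 1e-9)
  expect_equal(rd0$ci_high, rd0$rd_per_1000, tolerance = 1e-9)
})

test_that("simulation quantiles contain the point estimate and stabilise", {
  coh <- build_cohort(generate_registry(small_params(mean_births_per_day = 3,
                                                     seed = 109)))
  fit <- fit_hazard_model(coh, trend_order = 2)
  rd_a <- estimate_risk_differences(fit, horizons = c(5, 15, 30),
                                    n_sims = 50000, seed = 5)
  rd_b <- estimate_risk_differences(fit, horizons = c(5, 15, 30),
                                    n_sims = 100000, seed = 6)
  expect_true(all(rd_a$ci_low <= rd_a$rd_per_1000 + 1e-9))
  expect_true(all(rd_a$ci_high >= rd_a$rd_per_1000 - 1e-9))
  expect_true(all(abs(rd_a$ci_low - rd_b$ci_low) < 0.35))
  expect_true(all(abs(rd_a$ci_high - rd_b$ci_high) < 0.35))
  expect_error(estimate_risk_differences(fit, horizons = 50, n_sims = 200,
                                         seed = 1), "follow-up")
  expect_error(estimate_risk_differences(fit, n_sims = 50, seed = 1),
               "at least 100")
})

test_that("stratum with no events is rejected", {
  dat <- toy_cohort(t = c(1, 2, 3, 4), event = c(1L, 1L, 0L, 0L),
                    treated = c(0L, 0L, 1L, 1L))
  expect_error(fit_hazard_model(dat), "no events in stratum")
})
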