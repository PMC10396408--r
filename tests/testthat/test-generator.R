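test_that("degenerate birth rate yields an empty registry", {
  p <- small_params(mean_births_per_day = 0)
  reg <- generate_registry(p, seed = 1)
  expect_equal(nrow(reg), 0)
  expect_true(all(c("birth_date", "event_date", "censor_date") %in% names(reg)))
})

test_that("total birth count follows its Poisson law", {
  # 100 days at 10 births/day: the count must fall in the central 99%
  # Poisson band around 1000
  p <- generator_params(birth_window_start = "1984-01-01",
                        birth_window_end = "1984-04-09",
                        mean_births_per_day = 10, seed = 7)
  n_days <- as.numeric(as.Date("1984-04-09") - as.Date("1984-01-01")) + 1
  expect_equal(n_days, 100)
  reg <- generate_registry(p)
  band <- qpois(c(0.005, 0.995), 1000)
  expect_gte(nrow(reg), band[1])
  expect_lte(nrow(reg), band[2])
})

test_that("covariate prevalences are recovered within 3 Monte-Carlo SEs", {
  p <- generator_params(mean_births_per_day = 20, seed = 21)  # ~51k births
  reg <- generate_registry(p)
  n <- nrow(reg)
  expect_gt(n, 40000)
  mc <- function(q) 3 * sqrt(q * (1 - q) / n)
  expect_lt(abs(mean(reg$partnered) - 0.846), mc(0.846))
  expect_lt(abs(mean(reg$below_mean_income) - 0.452), mc(0.452))
  fe <- prop.table(table(reg$family_education))
  truth <- c(low = 0.214, intermediate = 0.472, high = 0.299, missing = 0.015)
  for (l in names(truth))
    expect_lt(abs(fe[[l]] - truth[[l]]), mc(truth[[l]]))
  expect_lt(abs(mean(reg$singleton) - 0.989), mc(0.989))
})

test_that("registry generation is byte-identical given params and seed", {
  p <- small_params(seed = 5)
  expect_identical(generate_registry(p, seed = 5), generate_registry(p, seed = 5))
  expect_false(identical(generate_registry(p, seed = 5),
                         generate_registry(p, seed = 6)))
})

test_that("mothers contribute multiple births with shared covariates", {
  reg <- generate_registry(small_params(mean_births_per_day = 6, seed = 3))
  counts <- table(reg$mother_id)
  expect_gt(max(counts), 1)
  multi <- names(counts[counts > 1])[1:50]
  for (m in multi) {
    rows <- reg[reg$mother_id == as.integer(m), ]
    expect_length(unique(rows$partnered), 1)
    expect_length(unique(as.character(rows$family_education)), 1)
  }
})

test_that("noiseless full-take-up leave is exactly baseline plus entitlement", {
  reg <- toy_registry(c("1984-02-10", "1984-03-25", "1984-03-26", "1984-05-01"))
  lv <- list(baseline_days = 98, pre_trend = 0, post_trend = 0,
             entitlement_extra_days = 42, takeup_probability = 1,
             noise_sd = 0, leave_observed_from = "1984-01-01",
             overrides = list())
  out <- assign_leave_days(reg, lv, cutoff = as.Date("1984-03-26"), seed = 2)
  expect_equal(out$leave_days, c(98, 98, 140, 140))
})

test_that("zero take-up leaves the leave profile continuous at the cut-off", {
  p <- generator_params(
    birth_window_start = "1984-01-01", birth_window_end = "1984-06-30",
    mean_births_per_day = 120, seed = 9,
    leave_params = list(takeup_probability = 0))
  reg <- generate_registry(p)
  coh <- build_cohort(reg, window_start = "1984-01-01",
                      window_end = "1984-06-30")
  fs <- estimate_leave_jump(coh)
  expect_lt(abs(fs$estimate), 3 * fs$se + 1e-9)
})

test_that("planted leave jump equals take-up times the entitlement extension", {
  # takeup 0.822, extra 39.96 days -> expected discontinuity 32.85 days
  p <- generator_params(
    birth_window_start = "1984-01-01", birth_window_end = "1984-06-30",
    mean_births_per_day = 250, seed = 13)
  reg <- generate_registry(p)
  coh <- build_cohort(reg, window_start = "1984-01-01",
                      window_end = "1984-06-30")
  fs <- estimate_leave_jump(coh)
  expect_lt(abs(fs$estimate - 32.85), 3 * fs$se)
})

test_that("exponential event times reproduce the closed-form incidence", {
  # constant 0.002/person-year, no competing censoring before 30 years:
  # 1-KM at 30y must be 1-exp(-0.06) within 3 MC SEs
  lam <- 0.002
  p <- generator_params(
    mean_births_per_day = 16, seed = 31,
    hazard_params = list(breaks = c(0, 30), control_rates = lam,
                         treated_rates = lam,
                         emigration_rate = 0, death_rate = 0))
  reg <- generate_registry(p)
  coh <- build_cohort(reg)
  km <- km_curves(coh)
  truth <- 1 - exp(-lam * 30)
  for (g in c("control", "treated")) {
    est <- km_cuminc_at(km, 30, g)
    n_g <- sum(coh$treated == (g == "treated"))
    expect_lt(abs(est - truth), 3 * sqrt(truth * (1 - truth) / n_g))
  }
})

test_that("null treatment effect gives equal incidence curves", {
  lam <- 0.004
  p <- generator_params(
    mean_births_per_day = 12, seed = 37,
    hazard_params = list(breaks = c(0, 30), control_rates = lam,
                         treated_rates = lam))
  coh <- build_cohort(generate_registry(p))
  km <- km_curves(coh)
  d30 <- km_cuminc_at(km, 30, "control") - km_cuminc_at(km, 30, "treated")
  se <- sqrt(sum(1 / c(sum(coh$treated == 0), sum(coh$treated == 1))) *
               0.11 * 0.89)
  expect_lt(abs(d30), 3 * se)
})

test_that("hazard-ratio calibration matches its closed form and an oracle", {
  # exponential baseline with 5-year control risk 2%, target 2.4 per 1000
  lam <- -log(0.98) / 5
  hr <- calibrate_hazard_ratio(2.4, 5, lam)
  expect_equal(hr, log(0.9824) / log(0.98), tolerance = 1e-12)
  # brute-force root-finding oracle on the defining equation
  f <- function(h) (1 - exp(-lam * 5)) - (1 - exp(-h * lam * 5)) - 0.0024
  hr_oracle <- uniroot(f, c(1e-6, 1), tol = 1e-12)$root
  expect_equal(hr, hr_oracle, tolerance = 1e-8)
  # piecewise baseline: planted risk difference is reproduced exactly
  prof <- default_incidence_profile()
  hr2 <- calibrate_hazard_ratio(3.8, 5,
                                list(breaks = prof$breaks,
                                     rates = prof$control_rates))
  H5 <- pexp_cumhaz(5, prof$breaks, prof$control_rates)
  expect_equal((1 - exp(-H5)) - (1 - exp(-hr2 * H5)), 0.0038,
               tolerance = 1e-12)
})

test_that("calibrated hazard ratio is null at target zero and monotone", {
  lam <- 0.005
  expect_equal(calibrate_hazard_ratio(0, 5, lam), 1, tolerance = 1e-12)
  hrs <- vapply(seq(-5, 15, by = 2.5), calibrate_hazard_ratio,
                numeric(1), horizon_years = 5, baseline = lam)
  expect_true(all(diff(hrs) < 0))
  expect_error(calibrate_hazard_ratio(1000 * (1 - exp(-lam * 5)) + 1, 5, lam),
               "unattainable")
})

test_that("incidence-profile calibration inverts exactly", {
  prof <- default_incidence_profile()
  expect_equal(-expm1(-pexp_cumhaz(prof$horizons, prof$breaks,
                                   prof$control_rates)),
               prof$control, tolerance = 1e-12)
  expect_equal(-expm1(-pexp_cumhaz(30, prof$breaks, prof$treated_rates)),
               0.0575, tolerance = 1e-12)
  expect_error(calibrate_rates_to_incidence(c(0.05, 0.04), c(0, 5, 10)),
               "increasing")
})

test_that("registry round-trips through CSV", {
  reg <- generate_registry(small_params(mean_births_per_day = 1, seed = 8))
  f <- tempfile(fileext = ".csv")
  write_registry(reg, f)
  back <- read_registry(f)
  expect_equal(back$birth_date, reg$birth_date)
  expect_equal(back$leave_days, reg$leave_days, tolerance = 1e-9)
  expect_equal(as.character(back$family_education),
               as.character(reg$family_education))
  expect_equal(back$event_date, reg$event_date)
  unlink(f)
})

test_that("scenario files reproduce generator parameters", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c(
    "mean_births_per_day: 3",
    "seed: 99",
    "leave_params:",
    "  takeup_probability: 0.5",
    "hazard_params:",
    "  emigration_rate: 0"), f)
  p <- read_scenario(f)
  expect_s3_class(p, "generator_params")
  expect_equal(p$leave_params$takeup_probability, 0.5)
  expect_equal(p$hazard_params$emigration_rate, 0)
  expect_identical(generate_registry(p), generate_registry(p))
  unlink(f)
})

test_that("invalid generator parameters are rejected", {
  expect_error(generator_params(birth_window_start = "1990-01-01",
                                birth_window_end = "1981-01-01"), "precede")
  expect_error(generator_params(
    leave_params = list(takeup_probability = 1.2)), "probability")
  expect_error(generator_params(
    covariate_prevalences = list(
      family_education = c(low = 0.5, intermediate = 0.5, high = 0.2,
                           missing = 0))), "sum to 1")
  expect_error(generator_params(
    hazard_params = list(control_rates = c(-1, 1, 1, 1, 1, 1))),
    "non-negative")
})
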