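#' Piecewise-exponential cumulative hazard
#'
#' @param t Numeric vector of follow-up times (years).
#' @param breaks Increasing numeric vector of interval endpoints starting at 0,
#'   e.g. `seq(0, 30, by = 5)`.
#' @param rates Non-negative rates (events per person-year), one per interval
#'   (`length(breaks) - 1`).  The last rate extends beyond the final break.
#' @return Cumulative hazard evaluated at `t`.
#' @export
pexp_cumhaz <- function(t, breaks, rates) {
  stopifnot(length(rates) == length(breaks) - 1L, breaks[1] == 0,
            all(diff(breaks) > 0))
  check_nonneg(rates, "rates")
  d <- diff(breaks)
  Hend <- cumsum(rates * d)
  j <- findInterval(t, breaks, rightmost.closed = FALSE)
  j <- pmin(pmax(j, 1L), length(rates))
  Hprev <- c(0, Hend)[j]
  Hprev + (t - breaks[j]) * rates[j]
}

## Inverse of pexp_cumhaz: smallest t with H(t) = h (vectorised in h).
pexp_cumhaz_inv <- function(h, breaks, rates) {
  d <- diff(breaks)
  Hend <- cumsum(rates * d)
  J <- length(rates)
  j <- findInterval(h, c(0, Hend), rightmost.closed = FALSE)
  j <- pmin(pmax(j, 1L), J)
  Hprev <- c(0, Hend)[j]
  r <- rates[j]
  out <- breaks[j] + ifelse(r > 0, (h - Hprev) / r, Inf)
  ## zero-rate plateaus that never reach h
  out[h > Hend[J] & rates[J] == 0] <- Inf
  out
}

#' Convert a cumulative-incidence profile into piecewise-constant hazard rates
#'
#' Given target cumulative incidences \eqn{F(t_j)} at the right endpoints of
#' consecutive intervals, returns the piecewise-constant rates that reproduce
#' them exactly under an exponential survival model:
#' \eqn{\lambda_j = (H_j - H_{j-1}) / (t_j - t_{j-1})} with
#' \eqn{H_j = -\log(1 - F_j)}.
#'
#' @param incidence Increasing vector of cumulative incidences in (0, 1), one
#'   per interval endpoint (excluding time 0).
#' @param breaks Interval endpoints starting at 0, length
#'   `length(incidence) + 1`.
#' @return Numeric vector of rates (events per person-year).
#' @export
calibrate_rates_to_incidence <- function(incidence, breaks = seq(0, 30, by = 5)) {
  stopifnot(length(breaks) == length(incidence) + 1L)
  check_prob(incidence, "incidence")
  if (any(diff(incidence) <= 0) || incidence[1] <= 0)
    stop("cumulative incidence must be strictly increasing and positive",
         call. = FALSE)
  H <- -log1p(-incidence)
  diff(c(0, H)) / diff(breaks)
}

#' Hazard ratio planting a target risk difference at a horizon
#'
#' Returns the proportional-hazards multiplier `HR` such that, under the given
#' piecewise-exponential control baseline, the treated cumulative incidence at
#' `horizon_years` is lower than the control one by `target_rd_per_1000 / 1000`:
#' \eqn{F_c(h) - F_t(h) = RD/1000} with
#' \eqn{F_t(h) = 1 - \exp(-HR \cdot H_c(h))}.  Under proportional hazards this
#' has the closed form \eqn{HR = \log(1 - F_t(h)) / \log(1 - F_c(h))}; the
#' treated incidence decreases when the target is positive.
#'
#' @param target_rd_per_1000 Target risk difference, control minus treated,
#'   per 1000 women (positive = protective effect).
#' @param horizon_years Horizon at which the difference is planted.
#' @param baseline Either a single constant rate or a list with `breaks` and
#'   `rates` describing the control piecewise-exponential baseline.
#' @return The hazard ratio (treated over control), a single number.
#' @examples
#' # control 5-year risk 2%, plant 2.4 fewer per 1000:
#' lambda <- -log(0.98) / 5
#' calibrate_hazard_ratio(2.4, 5, lambda)  # ~0.879
#' @export
calibrate_hazard_ratio <- function(target_rd_per_1000, horizon_years, baseline) {
  if (is.numeric(baseline) && length(baseline) == 1L)
    baseline <- list(breaks = c(0, horizon_years), rates = baseline)
  Hc <- pexp_cumhaz(horizon_years, baseline$breaks, baseline$rates)
  if (Hc <= 0) stop("control baseline has zero cumulative hazard at the horizon",
                    call. = FALSE)
  Fc <- -expm1(-Hc)
  Ft <- Fc - target_rd_per_1000 / 1000
  if (Ft <= 0 || Ft >= 1)
    stop(sprintf(
      "target RD %.3f per 1000 unattainable: control incidence at %.4g y is %.4f",
      target_rd_per_1000, horizon_years, Fc), call. = FALSE)
  log1p(-Ft) / log1p(-Fc)
}

#' Default planted cumulative-incidence profile
#'
#' The generator's reference truth: control and treated (eligible) cumulative
#' incidences of a first inpatient psychiatric diagnosis at 5-year horizons
#' over 30 years of follow-up, on the probability scale.  The control profile
#' rises steeply in the early post-partum years and reaches 59.5 per 1000 at
#' 30 years; the treated profile is lower by 2.4, 2.5, 2.0, 2.3, 1.8 per 1000
#' at 5-25 years and reaches 57.5 per 1000 at 30 years.
#'
#' @return List with `horizons`, `control`, `treated` (incidences), `breaks`,
#'   `control_rates`, `treated_rates`.
#' @export
default_incidence_profile <- function() {
  horizons <- seq(5, 30, by = 5)
  control <- c(0.020, 0.030, 0.038, 0.046, 0.053, 0.0595)
  treated <- control - c(2.4, 2.5, 2.0, 2.3, 1.8, 2.0) / 1000
  breaks <- c(0, horizons)
  list(horizons = horizons, control = control, treated = treated,
       breaks = breaks,
       control_rates = calibrate_rates_to_incidence(control, breaks),
       treated_rates = calibrate_rates_to_incidence(treated, breaks))
}
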