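#' Derive the birth-date eligibility cut-off of a leave reform
#'
#' A reform taking effect on `reform_date` also covers mothers whose
#' pre-reform entitlement, started at the child's birth, is still running on
#' the reform date.  The first eligible birth date is therefore
#' `reform_date - 7 * prior_entitlement_weeks + 1` days.  For the 1984 Danish
#' extension (reform 1 July 1984, prior entitlement 14 weeks) this gives
#' 26 March 1984.
#'
#' @param reform_date `Date` (or string) on which the reform took effect.
#' @param prior_entitlement_weeks Non-negative integer, the pre-reform leave
#'   entitlement in weeks.
#' @return A `Date`: the first birth date eligible for the extended leave.
#' @examples
#' derive_cutoff("1984-07-01", 14)  # 1984-03-26
#' @export
derive_cutoff <- function(reform_date, prior_entitlement_weeks) {
  reform_date <- as_date_strict(reform_date, "reform_date")
  stopifnot(length(reform_date) == 1L, prior_entitlement_weeks >= 0)
  reform_date - 7L * as.integer(prior_entitlement_weeks) + 1L
}

#' Specify a parental-leave reform
#'
#' Bundles the reform date, the prior and new entitlements, and the derived
#' birth-date eligibility cut-off.  Defaults describe the 1984 Danish
#' extension from 14 to 20 weeks of paid leave.
#'
#' @param reform_date Reform implementation date.
#' @param prior_entitlement_weeks,new_entitlement_weeks Entitlements in weeks;
#'   `new` must exceed `prior`.
#' @return An object of class `reform_spec` with fields `reform_date`,
#'   `prior_entitlement_weeks`, `new_entitlement_weeks`, `cutoff_date`, and
#'   `entitlement_extra_days` (the 42-day nominal extension).
#' @export
reform_spec <- function(reform_date = "1984-07-01",
                        prior_entitlement_weeks = 14L,
                        new_entitlement_weeks = 20L) {
  if (new_entitlement_weeks <= prior_entitlement_weeks)
    stop("new entitlement must exceed the prior entitlement", call. = FALSE)
  cutoff <- derive_cutoff(reform_date, prior_entitlement_weeks)
  structure(list(
    reform_date = as.Date(reform_date),
    prior_entitlement_weeks = as.integer(prior_entitlement_weeks),
    new_entitlement_weeks = as.integer(new_entitlement_weeks),
    cutoff_date = cutoff,
    entitlement_extra_days =
      7 * (as.integer(new_entitlement_weeks) - as.integer(prior_entitlement_weeks))
  ), class = "reform_spec")
}

#' @export
print.reform_spec <- function(x, ...) {
  cat("Parental-leave reform\n")
  cat("  reform date:        ", format(x$reform_date), "\n")
  cat("  entitlement (weeks):", x$prior_entitlement_weeks, "->",
      x$new_entitlement_weeks, "\n")
  cat("  eligibility cut-off:", format(x$cutoff_date),
      "(births on/after this date are eligible)\n")
  invisible(x)
}
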