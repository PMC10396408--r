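#' @keywords internal
"_PACKAGE"

DAYS_PER_YEAR <- 365.25

#' Convert a calendar interval to years
#'
#' All calendar-time to follow-up-time conversions in the package use
#' 365.25 days per year.
#'
#' @param from,to `Date` vectors.
#' @return Numeric vector of signed year differences `(to - from) / 365.25`.
#' @export
years_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / DAYS_PER_YEAR
}

as_date_strict <- function(x, what = "date") {
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (any(is.na(out) & !is.na(x))) {
    stop(sprintf("unparsable %s: %s", what,
                 paste(utils::head(x[is.na(out) & !is.na(x)], 3), collapse = ", ")),
         call. = FALSE)
  }
  out
}

## Derive a stream of child seeds from one master seed, staying inside the
## 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(offset)) %% 2147483646L) + 1L
}

with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop(sprintf("'%s' must be non-negative and finite", name), call. = FALSE)
  invisible(x)
}

check_shares <- function(x, name, tol = 1e-6) {
  check_prob(x, name)
  if (abs(sum(x) - 1) > tol)
    stop(sprintf("'%s' must sum to 1 (got %.6f)", name, sum(x)), call. = FALSE)
  invisible(x)
}
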