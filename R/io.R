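REGISTRY_COLUMNS <- c("mother_id", "child_id", "birth_date", "leave_days",
                      "leave_observed", "birthweight_class", "singleton",
                      "partnered", "family_education", "mother_education",
                      "below_mean_income", "prior_diagnosis", "event_date",
                      "censor_date", "censor_reason")

#' Write a birth registry to disk
#'
#' CSV (default) or Parquet, with ISO-8601 dates and empty/null missing
#' values (never sentinel numbers).  Parquet requires the `arrow` package.
#'
#' @param registry Data.frame of birth records.
#' @param path Output file; format inferred from the extension unless given.
#' @param format `"csv"` or `"parquet"`.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path,
                           format = if (grepl("\\.parquet$", path)) "parquet"
                                    else "csv") {
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for Parquet output", call. = FALSE)
    arrow::write_parquet(registry, path)
  } else {
    out <- registry
    for (col in names(out)) {
      if (inherits(out[[col]], "Date")) out[[col]] <- format(out[[col]], "%Y-%m-%d")
      if (is.factor(out[[col]])) out[[col]] <- as.character(out[[col]])
    }
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a birth registry written by [write_registry()]
#'
#' @param path CSV or Parquet file.
#' @return Data.frame with parsed dates, logicals and factors.
#' @export
read_registry <- function(path) {
  if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for Parquet input", call. = FALSE)
    reg <- as.data.frame(arrow::read_parquet(path))
  } else {
    reg <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  }
  for (col in intersect(c("birth_date", "event_date", "censor_date"), names(reg)))
    reg[[col]] <- as_date_strict(reg[[col]], col)
  for (col in intersect(c("leave_observed", "singleton", "partnered",
                          "below_mean_income", "prior_diagnosis"), names(reg)))
    reg[[col]] <- as.logical(reg[[col]])
  if ("birthweight_class" %in% names(reg))
    reg$birthweight_class <- factor(reg$birthweight_class,
                                    levels = c("low", "normal", "missing"))
  for (col in intersect(c("family_education", "mother_education"), names(reg)))
    reg[[col]] <- factor(reg[[col]],
                         levels = c("low", "intermediate", "high", "missing"))
  reg
}

#' Read a generator scenario file
#'
#' A YAML file whose top-level keys mirror the arguments of
#' [generator_params()] (including `seed`).
#'
#' @param path YAML scenario file.
#' @return A `generator_params` object.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  known <- names(formals(generator_params))
  unknown <- setdiff(names(sc), known)
  if (length(unknown))
    stop("unknown scenario keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ## YAML maps arrive as lists; collapse flat scalar maps to named vectors but
  ## leave nested structures (overrides, subgroup effects) intact
  flatten1 <- function(x) {
    if (is.list(x) && length(x) &&
        all(vapply(x, function(e) is.atomic(e) && length(e) == 1L, TRUE)))
      unlist(x) else x
  }
  for (k in c("covariate_prevalences", "leave_params", "hazard_params"))
    if (!is.null(sc[[k]])) {
      sc[[k]] <- lapply(sc[[k]], flatten1)
      if ("subgroup_treatment_log_hr" %in% names(sc[[k]]))
        sc[[k]]$subgroup_treatment_log_hr <-
          lapply(sc[[k]]$subgroup_treatment_log_hr, flatten1)
    }
  if (!is.null(sc$births_per_mother))
    sc$births_per_mother <- unlist(sc$births_per_mother)
  do.call(generator_params, sc)
}
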