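#' Pipeline configuration
#'
#' Assembles every setting of an end-to-end run.  Any field can be supplied
#' via a YAML file (`config_file`) and overridden by arguments, which take
#' precedence over file keys.
#'
#' @param registry_path Input registry CSV/Parquet; `NULL` when a generator
#'   `scenario` is supplied for a self-contained run.
#' @param out_dir Output directory for the report bundle.
#' @param scenario Optional `generator_params` (or path to a scenario YAML)
#'   used to simulate the registry in place of `registry_path`.
#' @param reform A [reform_spec()].
#' @param window_start,window_end,admin_censor_date Cohort settings.
#' @param trend_order,horizons,n_sims Model settings.
#' @param subgroup_factors Factors for the subgroup analyses.
#' @param placebo_cutoffs,bandwidth_months Robustness settings.
#' @param first_stage_window Window for the leave-jump estimate.
#' @param seed Master seed; every stochastic stage derives its own from it.
#' @param config_file Optional YAML file with the same keys.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(registry_path = NULL, out_dir = "leaverdd-out",
                            scenario = NULL,
                            reform = reform_spec(),
                            window_start = "1981-01-01",
                            window_end = "1987-12-31",
                            admin_censor_date = "2017-12-31",
                            trend_order = 2,
                            horizons = seq(5, 30, by = 5),
                            n_sims = 10000,
                            subgroup_factors = c("birthweight_class",
                                                 "partnered",
                                                 "family_education",
                                                 "below_mean_income"),
                            placebo_cutoffs = c("1982-03-26", "1983-03-26",
                                                "1986-03-26"),
                            bandwidth_months = c(12, 18, 24, 30, 36, 45),
                            first_stage_window = c("1984-02-01", "1984-05-31"),
                            seed = 1L,
                            config_file = NULL) {
  cfg <- as.list(environment())
  cfg$config_file <- NULL
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    supplied <- names(match.call())[-1]
    for (k in setdiff(names(file_cfg), c(supplied, "config_file")))
      cfg[[k]] <- file_cfg[[k]]
  }
  if (is.character(cfg$scenario)) cfg$scenario <- read_scenario(cfg$scenario)
  if (is.null(cfg$registry_path) && is.null(cfg$scenario))
    stop("either registry_path or a generator scenario is required",
         call. = FALSE)
  if (is.null(cfg$seed)) stop("a seed is mandatory", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Validate a birth-registry table
#'
#' Checks the column dictionary, date parsability and record invariants
#' (event/censor dates not before birth, non-negative leave, exactly one of
#' event/censoring per record).  Never mutates the data.
#'
#' @param registry Data.frame to validate.
#' @return An object of class `validation_report`: list with `n_rows`,
#'   `n_violations` and `violations`, a data.frame of (row, column, problem).
#' @export
validate_registry <- function(registry) {
  v <- list()
  flag <- function(rows, column, problem) {
    if (length(rows))
      v[[length(v) + 1]] <<- data.frame(row = rows, column = column,
                                        problem = problem,
                                        stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(c("mother_id", "child_id", "birth_date",
                            "event_date", "censor_date"), names(registry))
  if (length(missing_cols))
    flag(0L, missing_cols, "required column absent")

  parse_dates <- function(col) {
    if (!col %in% names(registry)) return(rep(as.Date(NA), nrow(registry)))
    x <- registry[[col]]
    if (inherits(x, "Date")) return(x)
    d <- as.Date(as.character(x), format = "%Y-%m-%d", optional = TRUE)
    flag(which(!is.na(x) & is.na(d)), col, "unparsable date")
    d
  }
  bd <- parse_dates("birth_date")
  ed <- parse_dates("event_date")
  cd <- parse_dates("censor_date")
  flag(which(!is.na(ed) & !is.na(bd) & ed < bd), "event_date",
       "event before birth")
  flag(which(!is.na(cd) & !is.na(bd) & cd < bd), "censor_date",
       "censoring before birth")
  flag(which(!is.na(ed) & !is.na(cd)), "event_date",
       "both event and censoring recorded")
  flag(which(!is.na(bd) & is.na(ed) & is.na(cd)), "event_date",
       "neither event nor censoring recorded")
  if ("leave_days" %in% names(registry)) {
    ld <- suppressWarnings(as.numeric(registry$leave_days))
    flag(which(!is.na(ld) & ld < 0), "leave_days", "negative leave")
  }
  if ("mother_id" %in% names(registry))
    flag(which(is.na(registry$mother_id)), "mother_id", "missing mother id")

  violations <- if (length(v)) do.call(rbind, v)
                else data.frame(row = integer(), column = character(),
                                problem = character(), stringsAsFactors = FALSE)
  structure(list(n_rows = nrow(registry), n_violations = nrow(violations),
                 violations = violations),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Registry validation: %d rows, %d violations\n",
              x$n_rows, x$n_violations))
  if (x$n_violations) print(utils::head(x$violations, 20), row.names = FALSE)
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Executes (optional) registry generation, validation, cohort construction,
#' first stage, density test, the survival-RDD risk-difference estimation,
#' subgroup analyses and robustness sweeps, and writes a report bundle to
#' `config$out_dir`: `summary.json`, tidy CSV tables (daily leave series,
#' cumulative-incidence curves, subgroup and sweep tables), the exclusion
#' log, a config echo with its MD5 hash, and `pipeline.log`.
#'
#' @param config A [pipeline_config()].
#' @param stages Subset of stages to run (default all).
#' @return Invisibly, the in-memory results list (also serialized to the
#'   bundle).
#' @export
run_pipeline <- function(config,
                         stages = c("first_stage", "density", "estimate",
                                    "subgroups", "placebo", "bandwidth",
                                    "sensitivity")) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "pipeline.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    cat(msg, "\n", file = logf, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    log_line("stage ", name, " start")
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                 file.path(config$out_dir, "FAILED"))
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  results <- list(package_version =
                    as.character(utils::packageVersion("leaverdd")),
                  seed = config$seed)

  ## config echo + hash
  cfg_file <- file.path(config$out_dir, "config.json")
  cfg_export <- config
  cfg_export$scenario <- if (is.null(config$scenario)) NULL else
    "generator scenario (see summary.json generator block)"
  cfg_export$reform <- lapply(unclass(config$reform), format)
  jsonlite::write_json(unclass(cfg_export), cfg_file, auto_unbox = TRUE,
                       null = "null", Date = "ISO8601", force = TRUE,
                       pretty = TRUE)
  ## hash over the analysis-relevant settings, invariant to where the
  ## bundle is written or the registry file lives
  hash_cfg <- cfg_export
  hash_cfg$out_dir <- hash_cfg$registry_path <- NULL
  hash_file <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(hash_cfg), hash_file, auto_unbox = TRUE,
                       null = "null", Date = "ISO8601", force = TRUE)
  results$config_hash <- unname(tools::md5sum(hash_file))
  unlink(hash_file)

  registry <- stage("input", {
    if (!is.null(config$scenario)) {
      log_line("generating synthetic registry (seed ",
               derive_seed(config$seed, 10L), ")")
      generate_registry(config$scenario, seed = derive_seed(config$seed, 10L),
                        cutoff = config$reform$cutoff_date)
    } else read_registry(config$registry_path)
  })
  results$validation <- stage("validate", {
    vr <- validate_registry(registry)
    if (vr$n_violations) log_line("validation: ", vr$n_violations, " violations")
    list(n_rows = vr$n_rows, n_violations = vr$n_violations)
  })
  cohort <- stage("cohort", {
    build_cohort(registry, reform = config$reform,
                 window_start = config$window_start,
                 window_end = config$window_end,
                 admin_censor_date = config$admin_censor_date)
  })
  results$cohort <- c(list(n = nrow(cohort),
                           mothers = length(unique(cohort$mother_id)),
                           exclusions = as.list(attr(cohort, "exclusions"))),
                      compute_followup(cohort)[c("person_years", "mean_years",
                                                 "median_years", "events")])
  jsonlite::write_json(as.list(attr(cohort, "exclusions")),
                       file.path(config$out_dir, "exclusions.json"),
                       auto_unbox = TRUE)

  if ("first_stage" %in% stages) {
    results$first_stage <- stage("first_stage", {
      fs <- estimate_leave_jump(cohort, window = config$first_stage_window)
      tk <- takeup_summary(cohort, window = config$first_stage_window)
      utils::write.csv(daily_mean_series(cohort, config$first_stage_window),
                       file.path(config$out_dir, "daily_leave_series.csv"),
                       row.names = FALSE)
      list(jump_days = fs$estimate, se = fs$se, ci = fs$ci,
           p_value = fs$p_value, n = fs$n,
           takeup_share = tk$share, takeup_share_threshold = tk$share_threshold)
    })
  }
  if ("density" %in% stages) {
    results$density_test <- stage("density", {
      dt <- density_test(registry, cutoff = config$reform$cutoff_date,
                         window = c(config$window_start, config$window_end))
      utils::write.csv(dt$bins,
                       file.path(config$out_dir, "birth_density_bins.csv"),
                       row.names = FALSE)
      list(log_rate_jump = dt$estimate, se = dt$se, p_value = dt$p_value)
    })
  }
  fit <- NULL
  if ("estimate" %in% stages) {
    results$risk_differences <- stage("estimate", {
      fit <- fit_hazard_model(cohort, trend_order = config$trend_order)
      rd <- estimate_risk_differences(fit, horizons = config$horizons,
                                      n_sims = config$n_sims,
                                      seed = derive_seed(config$seed, 20L))
      utils::write.csv(predict_cumulative_incidence(fit, at_u = 0),
                       file.path(config$out_dir, "cuminc_adjusted.csv"),
                       row.names = FALSE)
      utils::write.csv(km_curves(cohort),
                       file.path(config$out_dir, "cuminc_km.csv"),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(rd),
                       file.path(config$out_dir, "risk_differences.csv"),
                       row.names = FALSE)
      c(list(n_sims = attr(rd, "n_sims"), at_u = attr(rd, "at_u"),
             prediction = "at the cut-off (u = 0)"),
        list(table = as.data.frame(rd)))
    })
  }
  if ("subgroups" %in% stages) {
    results$subgroups <- stage("subgroups", {
      out <- list()
      for (f in config$subgroup_factors) {
        sg <- tryCatch(
          subgroup_rdd(cohort, f, horizons = config$horizons,
                       n_sims = config$n_sims,
                       seed = derive_seed(config$seed, 30L + match(f, config$subgroup_factors)),
                       trend_order = config$trend_order),
          error = function(e) { log_line("subgroup ", f, " skipped: ",
                                         conditionMessage(e)); NULL })
        if (is.null(sg)) next
        tab <- do.call(rbind, lapply(names(sg$levels), function(l) {
          d <- as.data.frame(sg$levels[[l]]); d$level <- l; d$factor <- f; d
        }))
        utils::write.csv(tab, file.path(config$out_dir,
                                        paste0("subgroup_", f, ".csv")),
                         row.names = FALSE)
        out[[f]] <- list(levels = lapply(sg$levels, function(r)
          as.list(as.data.frame(r)[1, c("horizon", "rd_per_1000",
                                        "ci_low", "ci_high")])),
          test = sg$test)
      }
      out
    })
  }
  if ("placebo" %in% stages) {
    results$placebo <- stage("placebo", {
      pl <- placebo_reforms(cohort, config$placebo_cutoffs,
                            n_sims = config$n_sims,
                            seed = derive_seed(config$seed, 40L),
                            trend_order = config$trend_order)
      utils::write.csv(as.data.frame(pl),
                       file.path(config$out_dir, "placebo_sweep.csv"),
                       row.names = FALSE)
      as.data.frame(pl)
    })
  }
  if ("bandwidth" %in% stages) {
    results$bandwidth <- stage("bandwidth", {
      bw <- bandwidth_sweep(cohort, config$bandwidth_months,
                            n_sims = config$n_sims,
                            seed = derive_seed(config$seed, 50L),
                            trend_order = config$trend_order)
      utils::write.csv(as.data.frame(bw),
                       file.path(config$out_dir, "bandwidth_sweep.csv"),
                       row.names = FALSE)
      as.data.frame(bw)
    })
  }
  if ("sensitivity" %in% stages) {
    results$sensitivity <- stage("sensitivity", {
      era <- era_adjusted_fit(cohort, horizons = config$horizons,
                              n_sims = config$n_sims,
                              seed = derive_seed(config$seed, 60L),
                              trend_order = config$trend_order)
      fb <- restrict_firstborn(cohort)
      fb_fit <- fit_hazard_model(fb, trend_order = config$trend_order)
      fb_rd <- estimate_risk_differences(fb_fit, horizons = config$horizons,
                                         n_sims = config$n_sims,
                                         seed = derive_seed(config$seed, 61L))
      list(era_coefficient = unname(era$fit$coefficients["era"]),
           era_rd = as.data.frame(era$rd),
           firstborn_n = nrow(fb),
           firstborn_rd = as.data.frame(fb_rd))
    })
  }

  jsonlite::write_json(results, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  log_line("pipeline complete")
  invisible(results)
}
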