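# Study orchestration: the 4x4 exposure-lag grid per outcome, stratified
# subgroup analyses with small-cell suppression, and tabular reports.

#' Configuration for a full study run
#'
#' @param outcomes Outcome groups to analyze.
#' @param heat_percentile Extreme-heat threshold percentile (90, 95, 99).
#' @param smoke_coding Smoke exposure coding: `"continuous"` (per
#'   microgram/m^3), `"binary_gt0"`, or `"binary_gt12"`.
#' @param months `"may_nov"` (wildfire/heat season, the primary analysis)
#'   or `"all"`.
#' @param years Optional integer vector of admission years to keep (after
#'   removing `exclude_years`).
#' @param exclude_years Years dropped from analysis (2020 by default).
#' @param strata_factors Subgroup factors for [run_stratified()]: any of
#'   sex, age_group, language, race_ethnicity, poverty, education,
#'   rurality.
#' @param suppression_min_exposed Cells with fewer exposed cases than
#'   this are suppressed (counts kept, no estimates).
#' @param exposed_rule How "cases exposed" is counted for suppression:
#'   `"joint"` (heat day and smoke > 0 at the assigned lags) or
#'   `"either"`.
#' @param delta Smoke increment for interaction measures, micrograms/m^3.
#' @param seed Seed recorded with the run (fitting is deterministic).
#' @return A `hs_run_config` list.
#' @export
run_config <- function(outcomes = c("all_natural", "respiratory",
                                    "cardiovascular", "cerebrovascular",
                                    "renal"),
                       heat_percentile = 95,
                       smoke_coding = c("continuous", "binary_gt0",
                                        "binary_gt12"),
                       months = c("may_nov", "all"),
                       years = NULL, exclude_years = 2020L,
                       strata_factors = character(),
                       suppression_min_exposed = 10L,
                       exposed_rule = c("joint", "either"),
                       delta = 1, seed = 1L) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  smoke_coding <- match.arg(smoke_coding)
  months <- match.arg(months)
  exposed_rule <- match.arg(exposed_rule)
  stopifnot(heat_percentile %in% c(90, 95, 99),
            suppression_min_exposed >= 0, delta > 0)
  ok_factors <- c("sex", "age_group", "language", "race_ethnicity",
                  "poverty", "education", "rurality")
  if (length(strata_factors) && !all(strata_factors %in% ok_factors)) {
    hs_stop("heatsmoke_config_error", "unknown strata factor(s): %s",
            paste(setdiff(strata_factors, ok_factors), collapse = ", "))
  }
  structure(list(outcomes = outcomes, heat_percentile = heat_percentile,
                 smoke_coding = smoke_coding, months = months,
                 years = years, exclude_years = as.integer(exclude_years),
                 strata_factors = strata_factors,
                 suppression_min_exposed = as.integer(suppression_min_exposed),
                 exposed_rule = exposed_rule, delta = delta,
                 seed = as.integer(seed)),
            class = "hs_run_config")
}

# Internal: count exposed cases on the case rows of a design table.
count_exposed <- function(design, rule) {
  cs <- design[design$is_case == TRUE]
  if (rule == "joint") {
    sum(cs$x_heat == 1 & cs$x_smoke > 0)
  } else {
    sum(cs$x_heat == 1 | cs$x_smoke > 0)
  }
}

# Internal: empty estimates row (for suppressed or failed cells).
empty_estimates <- function() {
  cols <- c("or01", "or01_lo", "or01_hi", "or01_p",
            "or10", "or10_lo", "or10_hi", "or10_p",
            "or11", "or11_lo", "or11_hi", "or11_p",
            "mult", "mult_lo", "mult_hi", "mult_p",
            "reri", "reri_se", "reri_lo", "reri_hi", "reri_p",
            "ap", "ap_se", "ap_lo", "ap_hi", "ap_p", "ap_p1", "delta")
  data.table::as.data.table(
    stats::setNames(as.list(rep(NA_real_, length(cols))), cols))
}

#' Run the 4x4 exposure-lag grid for each outcome
#'
#' For every requested outcome and each of the 16 (heat lag, smoke lag)
#' combinations, builds the case-crossover strata, fits the conditional
#' logistic interaction model and computes multiplicative and additive
#' interaction measures. Cells whose exposed-case count falls below the
#' suppression minimum carry counts but no estimates. Deterministic given
#' its inputs.
#'
#' @param cases Case records with zcta_id (or supply `zip_to_zcta`).
#' @param exposures Flagged ZCTA exposure series (zcta_id, date, tmax,
#'   wf_pm25, heat_day).
#' @param config A [run_config()].
#' @param zip_to_zcta Optional ZIP-to-ZCTA lookup.
#' @param subset_label Label recorded in the `subset` column.
#' @return `hs_lag_grid`: a data.table with one row per (outcome, heat
#'   lag, smoke lag) holding counts, suppression flags and estimates;
#'   attribute `accounting` holds per-outcome exclusion accounting.
#' @export
run_lag_grid <- function(cases, exposures, config = run_config(),
                         zip_to_zcta = NULL, subset_label = "all") {
  stopifnot(inherits(config, "hs_run_config"))
  cases <- data.table::as.data.table(cases)
  exposures <- data.table::as.data.table(exposures)
  n_input <- nrow(cases)

  n_excl_zip <- 0L
  if (!is.null(zip_to_zcta)) {
    cases <- assign_zcta(cases, zip_to_zcta)
    n_excl_zip <- attr(cases, "n_excluded_zip")
  } else if (!"zcta_id" %in% names(cases)) {
    hs_stop("heatsmoke_input_error",
            "cases lack zcta_id and no zip_to_zcta lookup was given")
  }

  # time filters decided on the case date
  n_before <- nrow(cases)
  if (config$months == "may_nov") {
    mo <- data.table::month(cases$admission_date)
    cases <- cases[mo >= 5L & mo <= 11L]
  }
  yr <- data.table::year(cases$admission_date)
  keep_yr <- !(yr %in% config$exclude_years)
  if (!is.null(config$years)) keep_yr <- keep_yr & yr %in% config$years
  cases <- cases[keep_yr]
  n_excl_time <- n_before - nrow(cases)

  outcome_m <- classify_outcome_matrix(cases$icd_code, cases$icd_version)
  grids <- list()
  accounting <- list()
  for (oc in config$outcomes) {
    sub <- cases[outcome_m[, oc]]
    if (!nrow(sub)) {
      warning(sprintf("no cases for outcome '%s'; empty grid", oc))
    }
    rows <- list()
    n_excl_exposure <- 0L
    for (hl in 0:3) for (sl in 0:3) {
      cell <- data.table::data.table(outcome = oc, subset = subset_label,
                                     heat_lag = hl, smoke_lag = sl)
      if (!nrow(sub)) {
        rows[[length(rows) + 1L]] <- cbind(
          cell, n_strata = 0L, n_exposed = 0L, suppressed = TRUE,
          converged = NA, note = "no cases", empty_estimates())
        next
      }
      design <- attach_lagged_exposures(sub, exposures, hl, sl,
                                        config$smoke_coding)
      n_excl_exposure <- max(n_excl_exposure,
                             attr(design, "n_excluded_exposure"))
      n_exposed <- count_exposed(design, config$exposed_rule)
      n_strata <- length(unique(design$stratum_id))
      if (n_exposed < config$suppression_min_exposed) {
        rows[[length(rows) + 1L]] <- cbind(
          cell, n_strata = n_strata, n_exposed = n_exposed,
          suppressed = TRUE, converged = NA, note = "suppressed",
          empty_estimates())
        next
      }
      res <- tryCatch({
        fit <- fit_clogit(design)
        if (!fit$converged) {
          cbind(cell, n_strata = n_strata, n_exposed = n_exposed,
                suppressed = FALSE, converged = FALSE,
                note = fit$diagnostic, empty_estimates())
        } else {
          est <- interaction_measures(fit, delta = config$delta)$estimates
          cbind(cell, n_strata = n_strata, n_exposed = n_exposed,
                suppressed = FALSE, converged = TRUE, note = NA_character_,
                est)
        }
      }, heatsmoke_error = function(e) {
        cbind(cell, n_strata = n_strata, n_exposed = n_exposed,
              suppressed = FALSE, converged = FALSE,
              note = conditionMessage(e), empty_estimates())
      })
      rows[[length(rows) + 1L]] <- res
    }
    grid <- data.table::rbindlist(rows, use.names = TRUE)
    grids[[oc]] <- grid
    accounting[[oc]] <- c(input = n_input, excluded_zip = n_excl_zip,
                          excluded_time = n_excl_time,
                          outcome_cases = nrow(sub),
                          excluded_exposure = n_excl_exposure)
  }
  out <- data.table::rbindlist(grids, use.names = TRUE)
  data.table::setattr(out, "accounting", accounting)
  data.table::setattr(out, "class",
                      c("hs_lag_grid", class(out)))
  out[]
}

# Internal: subgroup level definitions for a stratification factor.
factor_levels <- function(cases, factor) {
  switch(factor,
    sex = ,
    age_group = ,
    language = ,
    race_ethnicity = {
      lv <- sort(unique(cases[[factor]]))
      lapply(lv, function(v) list(label = paste(factor, v, sep = "="),
                                  idx = cases[[factor]] == v))
    },
    poverty = list(
      list(label = "poverty=high", idx = cases$high_poverty == TRUE),
      list(label = "poverty=lesser", idx = cases$high_poverty == FALSE)),
    education = list(
      list(label = "education=low", idx = cases$low_education == TRUE),
      list(label = "education=higher", idx = cases$low_education == FALSE)),
    rurality = list(
      list(label = "rurality=rural", idx = cases$rural == TRUE),
      list(label = "rurality=urban", idx = cases$rural == FALSE))
  )
}

#' Stratified subgroup lag grids
#'
#' Refits the full lag grid within each level of each requested
#' stratification factor (individual-level: sex, age group, preferred
#' language, race/ethnicity; community-level binary flags: high poverty,
#' low educational attainment, rurality). All three coefficients are
#' refit per subset. Suppression applies per cell within each level.
#'
#' @inheritParams run_lag_grid
#' @return `hs_lag_grid` data.table stacked over factor levels (the
#'   `subset` column labels them).
#' @export
run_stratified <- function(cases, exposures, config, zip_to_zcta = NULL) {
  stopifnot(inherits(config, "hs_run_config"))
  if (!length(config$strata_factors)) {
    hs_stop("heatsmoke_config_error", "config$strata_factors is empty")
  }
  cases <- data.table::as.data.table(cases)
  if (!is.null(zip_to_zcta)) {
    cases <- assign_zcta(cases, zip_to_zcta)
  }
  out <- list()
  for (f in config$strata_factors) {
    for (lv in factor_levels(cases, f)) {
      sub <- cases[which(lv$idx)]
      out[[lv$label]] <- run_lag_grid(sub, exposures, config,
                                      subset_label = lv$label)
    }
  }
  res <- data.table::rbindlist(out, use.names = TRUE)
  data.table::setattr(res, "class", c("hs_lag_grid", class(res)))
  res[]
}

#' Write tabular study reports
#'
#' Emits, per outcome, a CSV of the 4x4 attributable-proportion grid with
#' confidence intervals and p-values (the tabular twin of a lag-grid heat
#' map), one JSON file with every estimate, and a plain-text run log with
#' exclusion and suppression accounting.
#'
#' @param results A `hs_lag_grid` (from [run_lag_grid()] or
#'   [run_stratified()]), or a list of them (rbind-ed).
#' @param output_dir Directory to write into (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(results, output_dir) {
  if (is.data.frame(results)) {
    results <- data.table::as.data.table(results)
  } else if (is.list(results)) {
    results <- data.table::rbindlist(results, use.names = TRUE)
  }
  if (!nrow(results)) {
    hs_stop("heatsmoke_input_error", "empty results")
  }
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE)
  if (!ok) hs_stop("heatsmoke_io_error", "cannot create '%s'", output_dir)

  paths <- character()
  for (oc in unique(results$outcome)) {
    grid <- results[results$outcome == oc,
                    c("subset", "heat_lag", "smoke_lag", "n_strata",
                      "n_exposed", "suppressed", "ap", "ap_lo", "ap_hi",
                      "ap_p"),
                    with = FALSE]
    p <- file.path(output_dir, sprintf("ap_grid_%s.csv", oc))
    data.table::fwrite(grid, p)
    paths <- c(paths, p)
  }
  pj <- file.path(output_dir, "estimates.json")
  jsonlite::write_json(results, pj, dataframe = "rows", na = "null",
                       digits = NA, auto_unbox = TRUE)
  paths <- c(paths, pj)

  acct <- attr(results, "accounting")
  pl <- file.path(output_dir, "run_log.txt")
  lines <- c(sprintf("heatsmoke run report (%d grid cells)", nrow(results)))
  if (!is.null(acct)) {
    for (oc in names(acct)) {
      a <- acct[[oc]]
      lines <- c(lines, sprintf(
        "%s: input=%d excluded_zip=%d excluded_time=%d outcome_cases=%d excluded_exposure=%d",
        oc, a[["input"]], a[["excluded_zip"]], a[["excluded_time"]],
        a[["outcome_cases"]], a[["excluded_exposure"]]))
    }
  }
  lines <- c(lines, sprintf("suppressed cells: %d / %d",
                            sum(results$suppressed), nrow(results)))
  writeLines(lines, pl)
  paths <- c(paths, pl)
  invisible(paths)
}
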