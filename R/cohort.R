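# Case-crossover cohort construction: ZCTA assignment with hospital-ZIP
# fallback, time-stratified referent selection, and lag-pair exposure
# attachment.

#' Assign ZCTAs to case records
#'
#' Exposure is assigned by the patient's residential ZIP code mapped to
#' its ZCTA; when the residential ZIP has no ZCTA match, the hospital ZIP
#' is used instead; records with neither matched are excluded and
#' counted.
#'
#' @param cases Case records with residential_zip and hospital_zip.
#' @param zip_to_zcta Lookup table (zip, zcta_id).
#' @return `cases` with a `zcta_id` column, unmatched records dropped;
#'   attribute `n_excluded_zip` holds the exclusion count.
#' @export
assign_zcta <- function(cases, zip_to_zcta) {
  cases <- data.table::as.data.table(cases)
  zz <- data.table::as.data.table(zip_to_zcta)
  stopifnot_cols(zz, c("zip", "zcta_id"), "zip_to_zcta")
  out <- data.table::copy(cases)
  if ("zcta_id" %in% names(out)) out[, zcta_id := NULL]
  res <- zz$zcta_id[match(out$residential_zip, zz$zip)]
  hos <- zz$zcta_id[match(out$hospital_zip, zz$zip)]
  out[, zcta_id := data.table::fifelse(is.na(res), hos, res)]
  n_excl <- sum(is.na(out$zcta_id))
  out <- out[!is.na(zcta_id)]
  data.table::setattr(out, "n_excluded_zip", n_excl)
  out[]
}

#' Time-stratified referent days for a case day
#'
#' Referents are every other day in the same calendar month and year
#' sharing the case day's day of week — always 3 or 4 of them.
#'
#' @param case_date A `Date` (vectorized).
#' @return For a single date, a vector of referent dates; for several, a
#'   list of such vectors.
#' @export
build_referents <- function(case_date) {
  case_date <- as.Date(case_date)
  one <- function(d) {
    first <- as.Date(format(d, "%Y-%m-01"))
    nd <- .days_in_month(d)
    offset <- as.integer(d - first) %% 7L
    days <- first + seq(offset, nd - 1L, by = 7L)
    days[days != d]
  }
  if (length(case_date) == 1L) one(case_date) else lapply(case_date, one)
}

.days_in_month <- function(d) {
  first <- as.Date(format(d, "%Y-%m-01"))
  nxt <- seq(first, by = "1 month", length.out = 2L)[2L]
  as.integer(nxt - first)
}

# Internal, vectorized: long table of case + referent days per case.
expand_strata_days <- function(case_id, case_date) {
  first <- as.Date(paste0(format(case_date, "%Y-%m"), "-01"))
  # month length via the next month's first day, fully vectorized
  y <- data.table::year(case_date); m <- data.table::month(case_date)
  nxt <- as.Date(sprintf("%d-%02d-01", y + (m == 12L), (m %% 12L) + 1L))
  ndays <- as.integer(nxt - first)
  offset <- as.integer(case_date - first) %% 7L
  nref <- (ndays - 1L - offset) %/% 7L + 1L  # same-dow days in month
  out <- data.table::data.table(
    case_id = rep(case_id, nref),
    date = rep(first + offset, nref) + (sequence(nref) - 1L) * 7L
  )
  out[, is_case := date == rep(case_date, nref)]
  out
}

#' Attach lag-assigned exposures to case-crossover strata
#'
#' For each case and referent day, reads the heat indicator at
#' `date - heat_lag` and the smoke exposure at `date - smoke_lag` from
#' the ZCTA exposure series, under the chosen smoke coding. Strata with
#' any missing exposure are excluded and counted.
#'
#' @param cases Case records with case_id, admission_date, zcta_id.
#' @param exposures Exposure series with zcta_id, date, heat_day, wf_pm25.
#' @param heat_lag,smoke_lag Lag days in 0..3.
#' @param smoke_coding `"continuous"` (micrograms/m^3), `"binary_gt0"`,
#'   or `"binary_gt12"` (strictly greater-than cutoffs).
#' @return Long design table (stratum_id, case_id, zcta_id, date,
#'   is_case, x_heat, x_smoke), case row first within stratum; attribute
#'   `n_excluded_exposure` counts dropped strata.
#' @export
attach_lagged_exposures <- function(cases, exposures, heat_lag, smoke_lag,
                                    smoke_coding = c("continuous",
                                                     "binary_gt0",
                                                     "binary_gt12")) {
  smoke_coding <- match.arg(smoke_coding)
  stopifnot(heat_lag %in% 0:3, smoke_lag %in% 0:3)
  cases <- data.table::as.data.table(cases)
  exposures <- data.table::as.data.table(exposures)
  stopifnot_cols(cases, c("case_id", "admission_date", "zcta_id"), "cases")
  stopifnot_cols(exposures, c("zcta_id", "date", "heat_day", "wf_pm25"),
                 "exposures")

  days <- expand_strata_days(cases$case_id, cases$admission_date)
  days <- cases[, .(case_id, zcta_id)][days, on = "case_id"]

  ex <- exposures[, .(zcta_id, date, heat_day, wf_pm25)]
  days[, hdate := date - as.integer(heat_lag)]
  days[, sdate := date - as.integer(smoke_lag)]
  days[, x_heat := as.numeric(
    ex[days, on = .(zcta_id, date = hdate), x.heat_day])]
  days[, smoke_raw := ex[days, on = .(zcta_id, date = sdate), x.wf_pm25]]
  days[, x_smoke := switch(smoke_coding,
                           continuous = smoke_raw,
                           binary_gt0 = as.numeric(smoke_raw > 0),
                           binary_gt12 = as.numeric(smoke_raw > 12))]

  bad <- days[is.na(x_heat) | is.na(x_smoke), unique(case_id)]
  n_excl <- length(bad)
  out <- days[!case_id %in% bad,
              .(case_id, zcta_id, date, is_case, x_heat, x_smoke)]
  data.table::setorder(out, case_id, -is_case, date)
  out[, stratum_id := data.table::rleid(case_id)]
  data.table::setcolorder(out, c("stratum_id", "case_id", "zcta_id",
                                 "date", "is_case", "x_heat", "x_smoke"))
  data.table::setattr(out, "n_excluded_exposure", n_excl)
  out[]
}

#' Build analyzable strata for one outcome and lag pair
#'
#' Full cohort pipeline: ZCTA assignment (with hospital-ZIP fallback),
#' outcome selection by ICD code ranges, optional May-November and year
#' filters decided on the case date, referent expansion and lag-assigned
#' exposure attachment. Exclusions at each step are recorded in the
#' `accounting` attribute (input = analyzed + excluded at each gate).
#'
#' @param cases Case records (see [simulate_cases()]).
#' @param exposures Flagged exposure series (zcta_id, date, tmax,
#'   wf_pm25, heat_day).
#' @param outcome One of all_natural, respiratory, cardiovascular,
#'   cerebrovascular, renal; NULL keeps every record.
#' @param heat_lag,smoke_lag Lag pair (0..3).
#' @param smoke_coding Smoke exposure coding, see
#'   [attach_lagged_exposures()].
#' @param months `"all"` or `"may_nov"` (events restricted to May through
#'   November, decided on the case date; referents share the month by
#'   construction).
#' @param years Optional integer vector of admission years to keep.
#' @param zip_to_zcta Optional ZIP lookup; if omitted, `cases$zcta_id`
#'   must already be present.
#' @return Design table as from [attach_lagged_exposures()], with an
#'   `accounting` attribute.
#' @export
build_strata <- function(cases, exposures, outcome = NULL,
                         heat_lag = 0L, smoke_lag = 0L,
                         smoke_coding = "continuous",
                         months = c("may_nov", "all"), years = NULL,
                         zip_to_zcta = NULL) {
  months <- match.arg(months)
  cases <- data.table::as.data.table(cases)
  n_input <- nrow(cases)
  n_excl_zip <- 0L
  if (!is.null(zip_to_zcta)) {
    cases <- assign_zcta(cases, zip_to_zcta)
    n_excl_zip <- attr(cases, "n_excluded_zip")
  } else if (!"zcta_id" %in% names(cases)) {
    hs_stop("heatsmoke_input_error",
            "cases lack zcta_id and no zip_to_zcta lookup was given")
  }

  n_before <- nrow(cases)
  if (!is.null(outcome)) {
    stopifnot(outcome %in% .outcome_labels)
    m <- classify_outcome_matrix(cases$icd_code, cases$icd_version)
    cases <- cases[m[, outcome]]
  }
  n_excl_outcome <- n_before - nrow(cases)

  n_before <- nrow(cases)
  if (months == "may_nov") {
    mo <- data.table::month(cases$admission_date)
    cases <- cases[mo >= 5L & mo <= 11L]
  }
  if (!is.null(years)) {
    cases <- cases[data.table::year(admission_date) %in% years]
  }
  n_excl_time <- n_before - nrow(cases)

  design <- attach_lagged_exposures(cases, exposures, heat_lag, smoke_lag,
                                    smoke_coding)
  acct <- c(input = n_input, excluded_zip = n_excl_zip,
            excluded_outcome = n_excl_outcome,
            excluded_time = n_excl_time,
            excluded_exposure = attr(design, "n_excluded_exposure"),
            analyzed = length(unique(design$stratum_id)))
  data.table::setattr(design, "accounting", acct)
  design
}
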