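# Cohort construction: ICD outcome classification, ZCTA assignment,
# time-stratified referents, lag-assigned exposures.

test_that("ICD-10 codes classify per the outcome category ranges", {
  expect_setequal(classify_outcome("J45", 10),
                  c("all_natural", "respiratory"))
  expect_setequal(classify_outcome("J45.9", 10),
                  c("all_natural", "respiratory"))  # subcode inherits
  expect_setequal(classify_outcome("I63", 10),
                  c("all_natural", "cerebrovascular"))
  expect_setequal(classify_outcome("N17", 10),
                  c("all_natural", "renal"))
  expect_setequal(classify_outcome("I5A", 10),
                  c("all_natural", "cardiovascular"))
  # natural cause only
  expect_equal(classify_outcome("K35", 10), "all_natural")
  # injury / external cause: empty set
  expect_length(classify_outcome("S72", 10), 0)
  expect_length(classify_outcome("V43", 10), 0)
  expect_length(classify_outcome("Z51", 10), 0)
  expect_error(classify_outcome("4J5", 10),
               class = "heatsmoke_parse_error")
})

test_that("ICD-9 codes classify per the outcome category ranges", {
  expect_setequal(classify_outcome("466", 9), c("all_natural", "respiratory"))
  expect_setequal(classify_outcome("4661", 9), c("all_natural", "respiratory"))
  expect_setequal(classify_outcome("410", 9),
                  c("all_natural", "cardiovascular"))
  expect_setequal(classify_outcome("434", 9),
                  c("all_natural", "cerebrovascular"))
  expect_setequal(classify_outcome("584", 9), c("all_natural", "renal"))
  expect_equal(classify_outcome("250", 9), "all_natural")
  expect_length(classify_outcome("800", 9), 0)   # injury
  expect_length(classify_outcome("E812", 9), 0)  # external cause
  expect_length(classify_outcome("V27", 9), 0)   # supplemental
})

test_that("ZCTA assignment falls back to hospital ZIP, then excludes", {
  zz <- data.table::data.table(zip = c("90001", "90002"),
                               zcta_id = c("Z1", "Z2"))
  cases <- data.table::data.table(
    case_id = 1:3,
    residential_zip = c("90001", "99999", "98888"),
    hospital_zip = c("90002", "90002", "97777"))
  out <- assign_zcta(cases, zz)
  expect_equal(out$zcta_id, c("Z1", "Z2"))
  expect_equal(attr(out, "n_excluded_zip"), 1L)
})

test_that("referents share day of week, month and year and number 3 or 4", {
  # calendar enumeration: Wednesday 2015-07-15
  expect_equal(build_referents(as.Date("2015-07-15")),
               as.Date(c("2015-07-01", "2015-07-08",
                         "2015-07-22", "2015-07-29")))
  # leap day, Monday 2016-02-29
  expect_equal(build_referents(as.Date("2016-02-29")),
               as.Date(c("2016-02-01", "2016-02-08",
                         "2016-02-15", "2016-02-22")))
  set.seed(123)
  dates <- as.Date("2011-01-01") + sample.int(3650, 300)
  for (d in as.list(dates)) {
    r <- build_referents(d)
    expect_false(d %in% r)
    expect_true(length(r) %in% 3:4)
    expect_true(all(format(r, "%Y-%m") == format(d, "%Y-%m")))
    expect_true(all(data.table::wday(r) == data.table::wday(d)))
  }
})

test_that("referent selection is symmetric", {
  set.seed(9)
  dates <- as.Date("2013-01-01") + sample.int(2000, 100)
  for (d in as.list(dates)) {
    for (r in as.list(build_referents(d))) {
      expect_true(d %in% build_referents(r))
    }
  }
})

make_const_exposure <- function(zcta = "Z1",
                                from = as.Date("2015-06-01"),
                                to = as.Date("2015-08-31")) {
  d <- seq(from, to, by = "day")
  data.table::data.table(zcta_id = zcta, date = d, tmax = 80,
                         wf_pm25 = 0, heat_day = FALSE)
}

test_that("lag-assigned exposures read the right dates and coding", {
  ex <- make_const_exposure()
  ex[date == as.Date("2015-07-12"), `:=`(heat_day = TRUE, wf_pm25 = 12)]
  cases <- data.table::data.table(case_id = 1L,
                                  admission_date = as.Date("2015-07-15"),
                                  zcta_id = "Z1")
  # zero lags: read on the row's own date
  d0 <- attach_lagged_exposures(cases, ex, 0, 0)
  expect_equal(d0[is_case == TRUE, x_heat], 0)
  # heat lag 3: case day reads 2015-07-12
  d3 <- attach_lagged_exposures(cases, ex, 3, 0)
  expect_equal(d3[is_case == TRUE, x_heat], 1)
  # smoke lag 3 reads d-3 for referents too: referent 07-15+7=22 reads 07-19
  ds <- attach_lagged_exposures(cases, ex, 0, 3)
  expect_equal(ds[date == as.Date("2015-07-15"), x_smoke], 12)
  expect_equal(ds[date == as.Date("2015-07-22"), x_smoke], 0)
  # strict > 12 under the binary_gt12 coding: 12.0 is unexposed
  dg <- attach_lagged_exposures(cases, ex, 0, 3, smoke_coding = "binary_gt12")
  expect_equal(dg[date == as.Date("2015-07-15"), x_smoke], 0)
  dg0 <- attach_lagged_exposures(cases, ex, 0, 3, smoke_coding = "binary_gt0")
  expect_equal(dg0[date == as.Date("2015-07-15"), x_smoke], 1)
  # case row comes first within the stratum
  expect_true(d0[1, is_case])
})

test_that("strata missing exposure history are excluded and counted", {
  ex <- make_const_exposure(from = as.Date("2015-07-01"))
  cases <- data.table::data.table(
    case_id = 1:2,
    admission_date = as.Date(c("2015-07-02", "2015-07-20")),
    zcta_id = "Z1")
  # case 1 needs 2015-06-29 for lag 3: excluded
  d <- attach_lagged_exposures(cases, ex, 3, 3)
  expect_equal(attr(d, "n_excluded_exposure"), 1L)
  expect_equal(unique(d$case_id), 2L)
})

test_that("build_strata filters by month on the case date and accounts fully", {
  ex <- data.table::rbindlist(list(
    make_const_exposure(from = as.Date("2015-01-01"),
                        to = as.Date("2015-12-31"))))
  cases <- data.table::data.table(
    case_id = 1:4,
    admission_date = as.Date(c("2015-03-10", "2015-06-10",
                               "2015-07-10", "2015-12-10")),
    zcta_id = "Z1",
    icd_code = c("J45", "J45", "I63", "J45"),
    icd_version = 10L)
  d <- build_strata(cases, ex, outcome = "respiratory",
                    heat_lag = 1, smoke_lag = 2, months = "may_nov")
  acct <- attr(d, "accounting")
  expect_equal(unname(acct["input"]), 4L)
  expect_equal(unname(acct["excluded_outcome"]), 1L)
  expect_equal(unname(acct["excluded_time"]), 2L)
  expect_equal(unname(acct["analyzed"]), 1L)
  mo <- data.table::month(d[is_case == TRUE, date])
  expect_true(all(mo >= 5 & mo <= 11))
  # accounting identity
  expect_equal(unname(acct["input"]),
               unname(acct["excluded_outcome"] + acct["excluded_time"] +
                        acct["excluded_exposure"] + acct["analyzed"]))
})
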