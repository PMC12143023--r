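# Exposure construction: smoke-free baselines, wildfire attribution,
# regridding, population weighting, heat thresholds and flags.

dates3y <- seq(as.Date("2014-01-01"), as.Date("2016-12-31"), by = "day")

test_that("smoke-free baseline is the mean over plume-free calendar days", {
  v <- rep(5, length(dates3y))
  jul4 <- format(dates3y, "%m-%d") == "07-04"
  v[jul4] <- c(10, 12, 14)
  pm <- make_field(list(`1` = v), dates3y)
  pl <- make_plumes(pm)
  base <- smoke_free_baseline(pm, pl)
  b <- base[month == 7 & day == 4]
  expect_equal(b$expected_pm25, 12)
  expect_equal(b$n_obs, 3L)

  # plume-flagged year excluded from the mean
  pl2 <- make_plumes(pm, list(`1` = as.Date("2015-07-04")))
  b2 <- smoke_free_baseline(pm, pl2)[month == 7 & day == 4]
  expect_equal(b2$expected_pm25, 12)  # mean of 10, 14
  expect_equal(b2$n_obs, 2L)
})

test_that("baseline widens symmetrically when a calendar day is always smoky", {
  v <- rep(9, length(dates3y))
  jul4 <- format(dates3y, "%m-%d") == "07-04"
  v[jul4] <- 40
  pm <- make_field(list(`1` = v), dates3y)
  pl <- make_plumes(pm, list(`1` = dates3y[jul4]))
  b <- smoke_free_baseline(pm, pl)[month == 7 & day == 4]
  expect_equal(b$expected_pm25, 9)  # July 3/5 fallback, w = 1
  expect_equal(b$window, 1L)
  expect_equal(b$n_obs, 6L)
})

test_that("a cell smoky across the whole widening window is an error", {
  v <- rep(9, length(dates3y))
  pm <- make_field(list(`1` = v), dates3y)
  always <- format(dates3y, "%m") %in% c("06", "07", "08")
  pl <- make_plumes(pm, list(`1` = dates3y[always]))
  expect_error(smoke_free_baseline(pm, pl),
               class = "heatsmoke_baseline_error")
})

test_that("wildfire-influenced PM2.5 follows the subtraction rule", {
  d <- seq(as.Date("2014-01-01"), as.Date("2016-01-03"), by = "day")
  v <- rep(12, length(d))
  v[length(d) - 2] <- 20  # 2016-01-01 plume, above baseline
  v[length(d) - 1] <- 20  # 2016-01-02 no plume
  v[length(d)] <- 10      # 2016-01-03 plume, below baseline
  pm <- make_field(list(`1` = v), d)
  pl <- make_plumes(pm, list(`1` = as.Date(c("2016-01-01", "2016-01-03"))))
  base <- smoke_free_baseline(pm, pl)
  wf <- wf_influenced_pm25(pm, pl, base)
  expect_equal(wf[date == as.Date("2016-01-01"), value], 8)
  expect_equal(wf[date == as.Date("2016-01-02"), value], 0)
  expect_equal(wf[date == as.Date("2016-01-03"), value], 0)
  expect_true(all(wf$value >= 0))
})

test_that("wildfire PM2.5 is bounded by total and zero off plume", {
  cfg <- small_sim_config(seed = 13L)
  env <- generate_environment(cfg)
  base <- smoke_free_baseline(env$pm25, env$plumes)
  wf <- wf_influenced_pm25(env$pm25, env$plumes, base)
  j <- env$plumes[, .(cell_id, date, plume_present)][
    wf, on = c("cell_id", "date")]
  j[, total := env$pm25$value]
  expect_true(all(j$value >= 0))
  expect_true(all(j$value <= j$total + 1e-12))
  expect_true(all(j$value[!j$plume_present] == 0))
})

test_that("nearest-neighbor regrid replicates blocks and preserves values", {
  d <- as.Date("2020-01-01")
  f1 <- make_field(list(`1` = 5), d, nx = 1L, ny = 1L)
  r <- regrid_nearest(f1, 3L)
  expect_equal(nrow(r), 9L)
  expect_true(all(r$value == 5))
  expect_equal(attr(r, "nx"), 3L)

  # checkerboard 2x2 -> factor 2: quadrants constant, mean unchanged
  cb <- data.table::data.table(cell_id = 1:4, date = d, value = 1:4)
  data.table::setattr(cb, "nx", 2L); data.table::setattr(cb, "ny", 2L)
  r2 <- regrid_nearest(cb, 2L)
  expect_equal(nrow(r2), 16L)
  expect_equal(mean(r2$value), 2.5)
  expect_equal(sort(unique(r2$value)), 1:4)
  # fine cell (1,1) belongs to coarse cell 1; (4,4) to coarse cell 4
  expect_equal(r2[cell_id == 1, value], 1)
  expect_equal(r2[cell_id == 16, value], 4)
  # identity at factor 1
  expect_equal(regrid_nearest(cb, 1L)$value, cb$value)
})

test_that("population weighting is an exact convex combination", {
  d <- as.Date("2020-01-01")
  f <- data.table::data.table(cell_id = 1:2, date = d, value = c(0, 4))
  cw <- data.table::data.table(cell_id = 1:2, zcta_id = "Z1",
                               population = c(1, 3))
  expect_equal(population_weighted_zcta(f, cw)$value, 3.0)

  # uniform field -> the same value
  f2 <- data.table::data.table(cell_id = 1:2, date = d, value = 7)
  expect_equal(population_weighted_zcta(f2, cw)$value, 7)

  # random 5-cell ZCTA vs an independent dot-product oracle
  set.seed(4)
  f5 <- data.table::data.table(cell_id = 1:5, date = d, value = rnorm(5))
  cw5 <- data.table::data.table(cell_id = 1:5, zcta_id = "Z9",
                                population = runif(5, 10, 100))
  got <- population_weighted_zcta(f5, cw5)$value
  want <- sum(f5$value * cw5$population) / sum(cw5$population)
  expect_equal(got, want)
  expect_gte(got, min(f5$value)); expect_lte(got, max(f5$value))

  # zero-population ZCTA is an error naming the ZCTA
  cw0 <- data.table::data.table(cell_id = 1:2, zcta_id = "Z0",
                                population = c(0, 0))
  expect_error(population_weighted_zcta(f, cw0), "Z0",
               class = "heatsmoke_input_error")
})

test_that("adding a constant to every cell shifts every ZCTA by the same", {
  set.seed(8)
  d <- seq(as.Date("2020-01-01"), by = "day", length.out = 4)
  f <- data.table::CJ(cell_id = 1:6, date = d)
  f[, value := rnorm(.N)]
  cw <- data.table::data.table(cell_id = 1:6,
                               zcta_id = rep(c("A", "B"), each = 3),
                               population = runif(6, 1, 50))
  a <- population_weighted_zcta(f, cw)
  f2 <- data.table::copy(f)[, value := value + 2.5]
  b <- population_weighted_zcta(f2, cw)
  expect_equal(b$value, a$value + 2.5)
})

test_that("heat thresholds are interpolated order statistics", {
  # 100 values 1..100 in one (zcta, month): p95 -> 95.05 by hand;
  # dates cycle within July (pooling is by calendar month)
  s <- data.table::data.table(zcta_id = "Z1",
                              date = as.Date("2015-07-01") + (0:99 %% 31),
                              tmax = 1:100)
  th <- heat_thresholds(s, percentiles = c(90, 95, 99))
  expect_equal(th[percentile == 95, threshold_F], 95.05)
  # hand oracle: sorted order statistics, h = (n-1)p + 1
  h <- (100 - 1) * 0.90 + 1
  want90 <- floor(h) + (h - floor(h)) * 1  # values are 1..100: x_(k) = k
  expect_equal(th[percentile == 90, threshold_F], want90)

  # degenerate distribution: all thresholds equal the constant
  s2 <- data.table::copy(s)[, tmax := 66]
  th2 <- heat_thresholds(s2)
  expect_true(all(th2$threshold_F == 66))

  # monotonicity across percentiles on random data
  s3 <- data.table::copy(s)[, tmax := rnorm(.N, 80, 10)]
  th3 <- heat_thresholds(s3)
  wide <- data.table::dcast(th3, zcta_id + month ~ percentile,
                            value.var = "threshold_F")
  expect_true(all(wide$`90` <= wide$`95` & wide$`95` <= wide$`99`))

  # too few observations is an error listing the pool
  s4 <- s[1:10]
  expect_error(heat_thresholds(s4), "month 7",
               class = "heatsmoke_input_error")
})

test_that("heat-day flag uses a strict threshold comparison", {
  th <- data.table::data.table(zcta_id = "Z1", month = 7L,
                               percentile = 95, threshold_F = 90)
  s <- data.table::data.table(
    zcta_id = "Z1",
    date = as.Date(c("2015-07-01", "2015-07-02")),
    tmax = c(90, 90.1))
  out <- flag_extreme_heat(s, th, 95)
  expect_equal(out$heat_day, c(FALSE, TRUE))
  # missing threshold -> error
  s2 <- data.table::copy(s)[, date := as.Date(c("2015-08-01", "2015-08-02"))]
  expect_error(flag_extreme_heat(s2, th, 95),
               class = "heatsmoke_input_error")
})

test_that("about 5% of days exceed the 95th percentile threshold per pool", {
  cfg <- small_sim_config(seed = 17L)
  px <- small_pipeline(cfg)
  s <- data.table::copy(px$series)[, month := data.table::month(date)]
  frac <- s[, .(n = .N, k = sum(heat_day)), by = .(zcta_id, month)]
  # interpolation error: at most one day per pool away from the nominal 5%
  expect_true(all(abs(frac$k - 0.05 * frac$n) <= 1))
})
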