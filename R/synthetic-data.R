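# Synthetic study inputs with known ground truth.
#
# The generator emulates the data sources of a compound wildfire-smoke /
# extreme-heat hospitalization study: daily gridded maximum temperature
# with a seasonal cycle, daily gridded PM2.5 with episodic plume-driven
# spikes, binary plume masks, a static population surface, a grid-to-ZCTA
# crosswalk, and hospitalization records whose within-stratum case-day
# probabilities follow the conditional-logistic interaction model with
# configurable (beta_H, beta_S, beta_HS).

#' Ground-truth effect sizes for the synthetic data generator
#'
#' @param beta_H Log-odds of hospitalization per extreme-heat day.
#' @param beta_S Log-odds per 1 microgram/m^3 wildfire-influenced PM2.5.
#' @param beta_HS Log-odds interaction per (heat day x 1 microgram/m^3).
#' @param heat_lag,smoke_lag Lag days (0-3) at which the true effects act.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(beta_H = 0, beta_S = 0, beta_HS = 0,
                             heat_lag = 0L, smoke_lag = 0L) {
  stopifnot(is.finite(beta_H), is.finite(beta_S), is.finite(beta_HS),
            heat_lag %in% 0:3, smoke_lag %in% 0:3)
  structure(list(beta_H = beta_H, beta_S = beta_S, beta_HS = beta_HS,
                 heat_lag = as.integer(heat_lag),
                 smoke_lag = as.integer(smoke_lag)),
            class = "simulation_truth")
}

#' Configuration for the synthetic study generator
#'
#' Defaults describe a small but climatologically plausible Californian
#' setting: a mid-70s degF mean with a 20 degF summer-peaking seasonal
#' cycle, lognormal background PM2.5 around 8 micrograms/m^3, and plume
#' events concentrated in May-November that add roughly 15 micrograms/m^3.
#'
#' @param n_cells_x,n_cells_y Grid dimensions (cells).
#' @param date_start,date_end Study period; must span at least two full
#'   years so calendar-day baselines and monthly thresholds are estimable.
#' @param n_zctas Number of ZCTAs (contiguous blocks of cells).
#' @param seasonal_amplitude_F Seasonal half-amplitude of Tmax, degF.
#' @param mean_tmax_F Annual mean daily maximum temperature, degF.
#' @param tmax_noise_sd_F Day-to-day Gaussian noise SD of Tmax, degF.
#' @param spatial_gradient_F Total west-east Tmax gradient across the
#'   grid, degF (0 = spatially homogeneous climate).
#' @param baseline_pm25_mean,baseline_pm25_sd Lognormal background PM2.5
#'   mean and SD, micrograms/m^3.
#' @param plume_rate Expected plume events per cell per May-November season.
#' @param plume_pm25_boost PM2.5 added on plume days, micrograms/m^3
#'   (jittered by +/-25% per cell-day).
#' @param plume_mean_duration_days Mean duration of a plume run, days.
#' @param pm25_coarse_factor Integer >= 1; when > 1, PM2.5 is generated on
#'   a coarser grid and block-replicated to the fine grid, mirroring the
#'   resampling of a 3-km product onto a 1-km analysis grid.
#' @param pop_mean Mean cell population, persons.
#' @param n_cases Number of hospitalization records to simulate.
#' @param truth A [simulation_truth()] object.
#' @param heat_percentile Percentile defining extreme-heat days for the
#'   case generator (90, 95 or 99).
#' @param demographics Named list of categorical probability vectors for
#'   sex, age_group, language, race_ethnicity; defaults follow the
#'   demographic composition of California natural-cause admissions.
#' @param community_rates Named Bernoulli rates for ZCTA flags
#'   (high_poverty, low_education, rural).
#' @param outcome_mix Probabilities over outcome groups used to draw each
#'   record's diagnosis code.
#' @param seed Integer RNG seed; all generator output is a pure function
#'   of the configuration including this seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_cells_x = 12L, n_cells_y = 12L,
                              date_start = as.Date("2015-01-01"),
                              date_end = as.Date("2017-12-31"),
                              n_zctas = 8L,
                              seasonal_amplitude_F = 20,
                              mean_tmax_F = 75,
                              tmax_noise_sd_F = 5,
                              spatial_gradient_F = 0,
                              baseline_pm25_mean = 8,
                              baseline_pm25_sd = 4,
                              plume_rate = 2,
                              plume_pm25_boost = 15,
                              plume_mean_duration_days = 3,
                              pm25_coarse_factor = 1L,
                              pop_mean = 500,
                              n_cases = 10000L,
                              truth = simulation_truth(),
                              heat_percentile = 95,
                              demographics = NULL,
                              community_rates = NULL,
                              outcome_mix = NULL,
                              seed = 1L) {
  date_start <- as.Date(date_start); date_end <- as.Date(date_end)
  if (as.numeric(date_end - date_start) < 729) {
    hs_stop("heatsmoke_config_error",
            "date range must span at least two full years (got %s to %s)",
            date_start, date_end)
  }
  stopifnot(n_cells_x >= 1, n_cells_y >= 1,
            n_zctas >= 1, n_zctas <= n_cells_x * n_cells_y,
            tmax_noise_sd_F >= 0, baseline_pm25_mean > 0,
            baseline_pm25_sd >= 0, plume_rate >= 0, plume_pm25_boost >= 0,
            plume_mean_duration_days >= 1, pm25_coarse_factor >= 1,
            heat_percentile %in% c(90, 95, 99),
            inherits(truth, "simulation_truth"))
  if ((n_cells_x %% pm25_coarse_factor) || (n_cells_y %% pm25_coarse_factor)) {
    hs_stop("heatsmoke_config_error",
            "grid dimensions must be divisible by pm25_coarse_factor")
  }
  if (is.null(demographics)) {
    demographics <- list(
      sex = c(Male = 0.424, Female = 0.576),
      age_group = c("18-49" = 0.360, "50-64" = 0.238, "65+" = 0.402),
      language = c(English = 0.852, Spanish = 0.105, Other = 0.043),
      race_ethnicity = c(White = 0.498, Black = 0.092, Hispanic = 0.277,
                         Asian = 0.087, Other = 0.046)
    )
  }
  if (is.null(community_rates)) {
    community_rates <- c(high_poverty = 0.188, low_education = 0.318,
                         rural = 0.028)
  }
  if (is.null(outcome_mix)) {
    outcome_mix <- c(respiratory = 0.20, cardiovascular = 0.25,
                     cerebrovascular = 0.10, renal = 0.10, other = 0.35)
  }
  structure(list(
    n_cells_x = as.integer(n_cells_x), n_cells_y = as.integer(n_cells_y),
    date_start = date_start, date_end = date_end,
    n_zctas = as.integer(n_zctas),
    seasonal_amplitude_F = seasonal_amplitude_F, mean_tmax_F = mean_tmax_F,
    tmax_noise_sd_F = tmax_noise_sd_F,
    spatial_gradient_F = spatial_gradient_F,
    baseline_pm25_mean = baseline_pm25_mean,
    baseline_pm25_sd = baseline_pm25_sd,
    plume_rate = plume_rate, plume_pm25_boost = plume_pm25_boost,
    plume_mean_duration_days = plume_mean_duration_days,
    pm25_coarse_factor = as.integer(pm25_coarse_factor),
    pop_mean = pop_mean, n_cases = as.integer(n_cases),
    truth = truth, heat_percentile = heat_percentile,
    demographics = demographics, community_rates = community_rates,
    outcome_mix = outcome_mix, seed = as.integer(seed)
  ), class = "simulation_config")
}

# Internal: lognormal (meanlog, sdlog) matching a target mean and SD.
lnorm_params <- function(m, s) {
  if (s <= 0) return(c(meanlog = log(m), sdlog = 0))
  s2 <- log(1 + (s / m)^2)
  c(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate the synthetic gridded environment
#'
#' Produces every exposure-side input of the study: daily gridded maximum
#' temperature (seasonal sinusoid peaking mid-July plus Gaussian noise),
#' daily gridded total PM2.5 (lognormal background plus plume-day boosts),
#' a plume mask drawn as multi-day runs concentrated in May-November, a
#' static gridded population, a cell-to-ZCTA crosswalk (contiguous blocks,
#' each cell in exactly one ZCTA), and a ZIP-to-ZCTA lookup. Output is
#' deterministic given the configuration seed.
#'
#' @param config A [simulation_config()].
#' @return List with data.tables `tmax`, `pm25` (cell_id, date, value),
#'   `plumes` (cell_id, date, plume_present, density_class), `population`
#'   (cell_id, population), `crosswalk` (cell_id, zcta_id, population),
#'   `zip_to_zcta` (zip, zcta_id), and the echoed `config`. Gridded tables
#'   carry `nx`/`ny` attributes giving the grid geometry.
#' @export
generate_environment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, generate_environment_impl(config))
}

generate_environment_impl <- function(config) {
  nx <- config$n_cells_x; ny <- config$n_cells_y
  ncell <- nx * ny
  dates <- seq(config$date_start, config$date_end, by = "day")
  nd <- length(dates)

  # --- population & crosswalk -----------------------------------------
  pop <- pmax(1, round(rlnorm(ncell,
                              meanlog = lnorm_params(config$pop_mean,
                                                     config$pop_mean)[1],
                              sdlog = lnorm_params(config$pop_mean,
                                                   config$pop_mean)[2])))
  cell_id <- seq_len(ncell)
  zcta_idx <- ((cell_id - 1L) * config$n_zctas) %/% ncell + 1L
  zcta_id <- sprintf("Z%03d", zcta_idx)
  crosswalk <- data.table::data.table(cell_id = cell_id, zcta_id = zcta_id,
                                      population = as.numeric(pop))
  population <- data.table::data.table(cell_id = cell_id,
                                       population = as.numeric(pop))
  zip_to_zcta <- data.table::data.table(
    zip = sprintf("90%03d", seq_len(config$n_zctas)),
    zcta_id = sprintf("Z%03d", seq_len(config$n_zctas))
  )

  # --- daily maximum temperature --------------------------------------
  doy <- as.integer(strftime(dates, "%j"))
  seasonal <- config$mean_tmax_F +
    config$seasonal_amplitude_F * cos(2 * pi * (doy - 196) / 365.25)
  xpos <- ((cell_id - 1L) %% nx) + 1L
  cell_off <- config$spatial_gradient_F * (xpos - (nx + 1) / 2) / max(nx - 1, 1)
  tmax <- data.table::data.table(
    cell_id = rep(cell_id, each = nd),
    date = rep(dates, ncell),
    value = rep(seasonal, ncell) + rep(cell_off, each = nd) +
      (if (config$tmax_noise_sd_F > 0)
         rnorm(ncell * nd, 0, config$tmax_noise_sd_F) else 0)
  )

  # --- plume mask: multi-day runs in May-November ---------------------
  years <- sort(unique(data.table::year(dates)))
  plume_flag <- matrix(FALSE, nd, ncell)  # day x cell
  if (config$plume_rate > 0) {
    n_events <- rpois(ncell * length(years), config$plume_rate)
    ev_cell <- rep(rep(cell_id, each = length(years)), n_events)
    ev_year <- rep(rep(years, ncell), n_events)
    ne <- length(ev_cell)
    if (ne > 0) {
      season_start <- as.Date(sprintf("%d-05-01", ev_year))
      season_len <- as.numeric(as.Date(sprintf("%d-11-30", ev_year)) -
                                 season_start) + 1
      ev_start <- season_start + floor(runif(ne) * season_len)
      ev_dur <- 1L + rpois(ne, config$plume_mean_duration_days - 1)
      day_cell <- rep(ev_cell, ev_dur)
      day_date <- rep(ev_start, ev_dur) +
        (sequence(ev_dur) - 1L)
      keep <- day_date >= config$date_start & day_date <= config$date_end
      di <- as.integer(day_date[keep] - config$date_start) + 1L
      plume_flag[cbind(di, day_cell[keep])] <- TRUE
    }
  }

  # --- total PM2.5: lognormal background (+ coarse-grid option) -------
  f <- config$pm25_coarse_factor
  lp <- lnorm_params(config$baseline_pm25_mean, config$baseline_pm25_sd)
  if (f > 1L) {
    cnx <- nx %/% f; cny <- ny %/% f
    bg_coarse <- data.table::data.table(
      cell_id = rep(seq_len(cnx * cny), each = nd),
      date = rep(dates, cnx * cny),
      value = rlnorm(cnx * cny * nd, lp[1], lp[2])
    )
    data.table::setattr(bg_coarse, "nx", cnx)
    data.table::setattr(bg_coarse, "ny", cny)
    pm25 <- regrid_nearest(bg_coarse, f)
    data.table::setorder(pm25, cell_id, date)
  } else {
    pm25 <- data.table::data.table(
      cell_id = rep(cell_id, each = nd),
      date = rep(dates, ncell),
      value = rlnorm(ncell * nd, lp[1], lp[2])
    )
  }
  # plume_flag is day x cell; column-major vectorization matches the
  # cell-major (cell_id, then date) row order of the pm25 table
  boost_amt <- numeric(nd * ncell)
  plume_by_row <- c(plume_flag)
  np <- sum(plume_by_row)
  if (np > 0 && config$plume_pm25_boost > 0) {
    boost_amt[plume_by_row] <- config$plume_pm25_boost * runif(np, 0.75, 1.25)
  }
  pm25[, value := value + boost_amt]

  dens <- rep("none", nd * ncell)
  dens[plume_by_row & boost_amt <= 12] <- "light"
  dens[plume_by_row & boost_amt > 12 & boost_amt <= 16] <- "medium"
  dens[plume_by_row & boost_amt > 16] <- "heavy"
  plumes <- data.table::data.table(
    cell_id = rep(cell_id, each = nd),
    date = rep(dates, ncell),
    plume_present = plume_by_row,
    density_class = dens
  )

  for (x in list(tmax, pm25, plumes)) {
    data.table::setattr(x, "nx", nx)
    data.table::setattr(x, "ny", ny)
  }
  list(tmax = tmax, pm25 = pm25, plumes = plumes, population = population,
       crosswalk = crosswalk, zip_to_zcta = zip_to_zcta, config = config)
}

#' Simulate hospitalization records from the conditional-logistic model
#'
#' Draws each synthetic case by (1) selecting a ZCTA and a
#' (year, month, day-of-week) referent stratum uniformly at random among
#' strata with at least two eligible days, then (2) selecting the
#' admission day within the stratum with probability proportional to
#' `exp(bH*Xheat + bS*Xsmoke + bHS*Xheat*Xsmoke)` evaluated at the truth
#' lags — exactly the data-generating process a conditional logistic
#' regression on time-stratified case-crossover strata assumes.
#' Demographics, diagnosis codes (drawn from the outcome code ranges, ICD
#' version switching in October 2015) and ZCTA community flags follow the
#' configured categorical distributions.
#'
#' @param config A [simulation_config()] (`truth` supplies the betas/lags).
#' @param exposure ZCTA-day exposure table with columns zcta_id, date,
#'   tmax, wf_pm25 and (optionally) heat_day.
#' @param thresholds Optional [heat_thresholds()] table; required when
#'   `exposure` lacks a heat_day column.
#' @param zip_to_zcta Optional zip lookup used to emit residential ZIPs;
#'   defaults to ZIP == ZCTA id.
#' @return data.table of case records; attribute `n_strata_ineligible`
#'   counts (zcta, year, month, dow) strata excluded for having fewer
#'   than two eligible days.
#' @export
simulate_cases <- function(config, exposure, thresholds = NULL,
                           zip_to_zcta = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  exposure <- data.table::as.data.table(exposure)
  stopifnot_cols(exposure, c("zcta_id", "date", "wf_pm25"), "exposure")
  if (!"heat_day" %in% names(exposure)) {
    if (is.null(thresholds)) {
      hs_stop("heatsmoke_input_error",
              "exposure lacks heat_day and no thresholds were supplied")
    }
    exposure <- flag_extreme_heat(exposure, thresholds,
                                  percentile = config$heat_percentile)
  }
  with_seed(config$seed + 1L,
            simulate_cases_impl(config, exposure, zip_to_zcta))
}

simulate_cases_impl <- function(config, exposure, zip_to_zcta) {
  tr <- config$truth
  ex <- data.table::copy(exposure)
  data.table::setorder(ex, zcta_id, date)
  ex[, `:=`(
    xh = as.numeric(data.table::shift(heat_day, tr$heat_lag)),
    xs = data.table::shift(wf_pm25, tr$smoke_lag)
  ), by = zcta_id]
  ex <- ex[!is.na(xh) & !is.na(xs) &
             date >= config$date_start + 3L]
  ex[, `:=`(yr = data.table::year(date), mo = data.table::month(date),
            dow = data.table::wday(date))]
  ex[, g := .GRP, by = .(zcta_id, yr, mo, dow)]
  data.table::setorder(ex, g, date)
  sizes <- ex[, .N, by = g]
  eligible <- sizes[N >= 2L, g]
  n_inelig <- nrow(sizes) - length(eligible)
  if (!length(eligible)) {
    hs_stop("heatsmoke_config_error", "no stratum has >= 2 eligible days")
  }
  ex <- ex[g %in% eligible]
  ex[, g := .GRP, by = g]  # recompact 1..G in date order
  ex[, w := exp(tr$beta_H * xh + tr$beta_S * xs + tr$beta_HS * xh * xs)]

  cs <- cumsum(ex$w)
  gstart <- ex[, .(first = min(.I), tot = sum(w)), by = g]
  base <- c(0, cs)[gstart$first]  # cumulative mass before each group

  n <- config$n_cases
  gi <- sample.int(nrow(gstart), n, replace = TRUE)
  u <- runif(n)
  pick <- findInterval(base[gi] + u * gstart$tot[gi], cs) + 1L
  picked <- ex[pick]

  draw_cat <- function(p, n) {
    names(p)[1L + findInterval(runif(n), cumsum(p) / sum(p))]
  }
  dem <- config$demographics
  zctas <- sort(unique(exposure$zcta_id))
  cr <- config$community_rates
  zflags <- data.table::data.table(
    zcta_id = zctas,
    high_poverty = runif(length(zctas)) < cr[["high_poverty"]],
    low_education = runif(length(zctas)) < cr[["low_education"]],
    rural = runif(length(zctas)) < cr[["rural"]]
  )

  # diagnosis codes: outcome group then a category from its printed ranges
  grp <- draw_cat(config$outcome_mix, n)
  ver <- ifelse(picked$date >= as.Date("2015-10-01"), 10L, 9L)
  code <- character(n)
  for (v in c(9L, 10L)) {
    for (lab in unique(grp)) {
      idx <- which(grp == lab & ver == v)
      if (!length(idx)) next
      cats <- if (lab == "other") {
        if (v == 10L) .other_natural_codes$icd10 else .other_natural_codes$icd9
      } else icd_categories(lab, v)
      code[idx] <- cats[sample.int(length(cats), length(idx), replace = TRUE)]
    }
  }

  if (is.null(zip_to_zcta)) {
    zip_of <- function(z) z
  } else {
    zz <- data.table::as.data.table(zip_to_zcta)
    first_zip <- zz[, .(zip = zip[1L]), by = zcta_id]
    zip_of <- function(z) first_zip[match(z, zcta_id), zip]
  }

  cases <- data.table::data.table(
    case_id = seq_len(n),
    admission_date = picked$date,
    residential_zip = zip_of(picked$zcta_id),
    hospital_zip = zip_of(picked$zcta_id[sample.int(n)]),
    icd_code = code,
    icd_version = ver,
    sex = draw_cat(dem$sex, n),
    age_group = draw_cat(dem$age_group, n),
    language = draw_cat(dem$language, n),
    race_ethnicity = draw_cat(dem$race_ethnicity, n),
    zcta_id = picked$zcta_id
  )
  cases <- zflags[cases, on = "zcta_id"]
  data.table::setcolorder(cases, c("case_id", "admission_date"))
  data.table::setorder(cases, case_id)
  data.table::setattr(cases, "n_strata_ineligible", n_inelig)
  cases[]
}

#' Simulate bare case-crossover strata for parameter-recovery studies
#'
#' A lightweight stratum-level data-generating process that skips the
#' gridded pipeline: each stratum holds one case and `n_referents`
#' referent days, exposures are drawn i.i.d. per day (heat Bernoulli,
#' smoke a Bernoulli-Exponential mixture), and the case day is selected
#' with the conditional-logistic probabilities implied by `beta`.
#'
#' @param n_strata Number of matched strata.
#' @param beta Numeric length-3 truth `(beta_H, beta_S, beta_HS)`.
#' @param n_referents Referent days per stratum (3 or 4 in a
#'   time-stratified monthly design).
#' @param p_heat Probability a day is an extreme-heat day.
#' @param p_smoke Probability of nonzero wildfire smoke on a day.
#' @param smoke_mean Mean wildfire-influenced PM2.5 (micrograms/m^3) on
#'   smoke-exposed days.
#' @param seed Optional seed.
#' @return Design data.table: stratum_id, is_case, x_heat, x_smoke.
#' @export
simulate_strata <- function(n_strata, beta, n_referents = 4L,
                            p_heat = 0.2, p_smoke = 0.25, smoke_mean = 2,
                            seed = NULL) {
  stopifnot(length(beta) == 3L, n_strata >= 1, n_referents >= 1)
  run <- function() {
    m <- n_referents + 1L
    n <- n_strata * m
    xh <- as.numeric(runif(n) < p_heat)
    xs <- ifelse(runif(n) < p_smoke, rexp(n, 1 / smoke_mean), 0)
    eta <- beta[1] * xh + beta[2] * xs + beta[3] * xh * xs
    w <- exp(eta)
    sid <- rep(seq_len(n_strata), each = m)
    cs <- cumsum(w)
    tot <- rowsum(w, sid, reorder = FALSE)[, 1]
    base <- c(0, cs)[seq(1L, n, by = m)]
    pick <- findInterval(base + runif(n_strata) * tot, cs) + 1L
    is_case <- logical(n)
    is_case[pick] <- TRUE
    data.table::data.table(stratum_id = sid, is_case = is_case,
                           x_heat = xh, x_smoke = xs)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
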