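# ZCTA-level daily exposure construction: wildfire-influenced PM2.5 via
# smoke-free calendar-day baselines, nearest-neighbor regridding,
# population-weighted aggregation, and percentile heat thresholds.

# Internal: (month, day) for each index of the fixed 365-day calendar.
.mdays365 <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
doy_to_month_day <- function(doy) {
  cum <- cumsum(c(0L, .mdays365))
  m <- findInterval(doy - 1L, cum[1:12])
  list(month = m, day = doy - cum[m])
}

#' Expected smoke-free PM2.5 baseline per grid cell and calendar day
#'
#' For each (cell, month, day-of-month) the baseline is the mean of total
#' PM2.5 over all study years on that calendar day restricted to days
#' with no smoke plume overhead. Calendar days with no smoke-free
#' observation widen symmetrically (plus/minus w days on a circular
#' 365-day calendar, w = 1, 2, ..., 15) until at least one smoke-free
#' observation is pooled. Feb 29 pools with Feb 28.
#'
#' @param pm25 Gridded daily total PM2.5 (cell_id, date, value).
#' @param plumes Plume mask (cell_id, date, plume_present).
#' @param max_widen Maximum window half-width, days.
#' @return data.table: cell_id, month, day, doy, expected_pm25, n_obs,
#'   window (half-width used).
#' @export
smoke_free_baseline <- function(pm25, plumes, max_widen = 15L) {
  pm25 <- data.table::as.data.table(pm25)
  plumes <- data.table::as.data.table(plumes)
  stopifnot_cols(pm25, c("cell_id", "date", "value"), "pm25")
  stopifnot_cols(plumes, c("cell_id", "date", "plume_present"), "plumes")

  x <- plumes[, .(cell_id, date, plume_present)][pm25, on = c("cell_id", "date")]
  if (anyNA(x$plume_present)) {
    hs_stop("heatsmoke_input_error",
            "plume mask does not cover every (cell, date) of the PM2.5 field")
  }
  x[, doy := month_day_key(date)]
  sf <- x[plume_present == FALSE,
          .(s = sum(value), n = .N), by = .(cell_id, doy)]

  cells <- sort(unique(x$cell_id))
  ci <- match(sf$cell_id, cells)
  S <- matrix(0, length(cells), 365L)
  C <- matrix(0L, length(cells), 365L)
  S[cbind(ci, sf$doy)] <- sf$s
  C[cbind(ci, sf$doy)] <- sf$n

  circ_window <- function(M, w) {
    if (w == 0L) return(M)
    idx <- c((365L - w + 1L):365L, 1:365, 1:w)
    P <- M[, idx, drop = FALSE]
    CS <- t(apply(P, 1L, cumsum))
    k <- 2L * w + 1L
    CS[, (k):(k + 364L), drop = FALSE] -
      cbind(0, CS[, 1:(364L + k - 1L), drop = FALSE])[, 1:365, drop = FALSE]
  }

  expected <- matrix(NA_real_, length(cells), 365L)
  n_obs <- matrix(0L, length(cells), 365L)
  window <- matrix(NA_integer_, length(cells), 365L)
  unresolved <- matrix(TRUE, length(cells), 365L)
  for (w in 0:max_widen) {
    Ws <- circ_window(S, w)
    Wc <- circ_window(C, w)
    fill <- unresolved & Wc >= 1L
    expected[fill] <- (Ws / Wc)[fill]
    n_obs[fill] <- Wc[fill]
    window[fill] <- w
    unresolved <- unresolved & !fill
    if (!any(unresolved)) break
  }
  if (any(unresolved)) {
    bad <- cells[unique(which(unresolved, arr.ind = TRUE)[, 1L])]
    hs_stop("heatsmoke_baseline_error",
            "no smoke-free observation within +/-%d days for cell(s): %s",
            max_widen, paste(bad, collapse = ", "))
  }

  md <- doy_to_month_day(1:365)
  out <- data.table::data.table(
    cell_id = rep(cells, times = 365L),
    month = rep(md$month, each = length(cells)),
    day = rep(md$day, each = length(cells)),
    doy = rep(1:365, each = length(cells)),
    expected_pm25 = c(expected),
    n_obs = c(n_obs),
    window = c(window)
  )
  data.table::setorder(out, cell_id, doy)
  out[]
}

#' Wildfire-influenced PM2.5
#'
#' Attributes PM2.5 to wildfire smoke by baseline subtraction: on days
#' when a smoke plume overlaps the cell and total PM2.5 exceeds the
#' expected smoke-free value, the wildfire-influenced concentration is
#' total minus expected; otherwise zero.
#'
#' @param pm25 Gridded daily total PM2.5 (cell_id, date, value).
#' @param plumes Plume mask (cell_id, date, plume_present).
#' @param baseline Output of [smoke_free_baseline()].
#' @return Gridded daily field (cell_id, date, value) with value >= 0.
#' @export
wf_influenced_pm25 <- function(pm25, plumes, baseline) {
  pm25 <- data.table::as.data.table(pm25)
  plumes <- data.table::as.data.table(plumes)
  baseline <- data.table::as.data.table(baseline)
  out <- plumes[, .(cell_id, date, plume_present)][
    pm25, on = c("cell_id", "date")]
  out[, doy := month_day_key(date)]
  out <- baseline[, .(cell_id, doy, expected_pm25)][
    out, on = c("cell_id", "doy")]
  if (anyNA(out$expected_pm25)) {
    hs_stop("heatsmoke_input_error",
            "baseline unresolved for some (cell, calendar day)")
  }
  out[, value := ifelse(plume_present & value > expected_pm25,
                        value - expected_pm25, 0)]
  res <- out[, .(cell_id, date, value)]
  data.table::setorder(res, cell_id, date)
  data.table::setattr(res, "nx", attr(pm25, "nx"))
  data.table::setattr(res, "ny", attr(pm25, "ny"))
  res[]
}

#' Nearest-neighbor regrid of a gridded field to a finer resolution
#'
#' Each fine cell takes the value of its containing coarse cell (block
#' replication), matching nearest-neighbor resampling of nested grids.
#' The multiset of distinct values is unchanged and block means equal the
#' coarse values.
#'
#' @param field Gridded daily field with `nx`/`ny` attributes.
#' @param factor Integer refinement factor (1 = identity).
#' @return Gridded field on the (nx*factor) x (ny*factor) grid.
#' @export
regrid_nearest <- function(field, factor) {
  field <- data.table::as.data.table(field)
  nx <- attr(field, "nx"); ny <- attr(field, "ny")
  if (is.null(nx) || is.null(ny)) {
    hs_stop("heatsmoke_input_error", "field lacks nx/ny grid attributes")
  }
  factor <- as.integer(factor)
  if (factor < 1L) hs_stop("heatsmoke_input_error", "factor must be >= 1")
  if (factor == 1L) {
    out <- data.table::copy(field)
    data.table::setattr(out, "nx", nx); data.table::setattr(out, "ny", ny)
    return(out)
  }
  ncell <- nx * ny
  nx2 <- nx * factor
  cid <- seq_len(ncell)
  cx <- ((cid - 1L) %% nx) + 1L
  cy <- ((cid - 1L) %/% nx) + 1L
  offs <- expand.grid(dx = seq_len(factor), dy = seq_len(factor))
  map <- data.table::data.table(
    cell_id = rep(cid, each = nrow(offs)),
    fx = rep(cx - 1L, each = nrow(offs)) * factor + offs$dx,
    fy = rep(cy - 1L, each = nrow(offs)) * factor + offs$dy
  )
  map[, fine_id := (fy - 1L) * nx2 + fx]
  out <- map[, .(cell_id, fine_id)][field, on = "cell_id",
                                    allow.cartesian = TRUE]
  out <- out[, .(cell_id = fine_id, date, value)]
  data.table::setorder(out, cell_id, date)
  data.table::setattr(out, "nx", nx2)
  data.table::setattr(out, "ny", ny * factor)
  out[]
}

#' Population-weighted aggregation of a gridded field to ZCTAs
#'
#' The ZCTA-day value is the population-share weighted mean of its cells:
#' `sum(value * pop_cell) / pop_zcta` — a convex combination, so ZCTA
#' values always lie within the range of their member cells.
#'
#' @param field Gridded daily field (cell_id, date, value).
#' @param crosswalk Cell-to-ZCTA crosswalk (cell_id, zcta_id, population).
#' @param value_name Name for the aggregated value column.
#' @return data.table (zcta_id, date, <value_name>).
#' @export
population_weighted_zcta <- function(field, crosswalk, value_name = "value") {
  field <- data.table::as.data.table(field)
  crosswalk <- data.table::as.data.table(crosswalk)
  stopifnot_cols(crosswalk, c("cell_id", "zcta_id", "population"), "crosswalk")
  tot <- crosswalk[, .(pop = sum(population)), by = zcta_id]
  if (any(tot$pop <= 0)) {
    hs_stop("heatsmoke_input_error", "ZCTA(s) with zero population: %s",
            paste(tot$zcta_id[tot$pop <= 0], collapse = ", "))
  }
  cw <- tot[crosswalk, on = "zcta_id"]
  cw[, wgt := population / pop]
  x <- cw[, .(cell_id, zcta_id, wgt)][field, on = "cell_id",
                                      allow.cartesian = TRUE]
  if (anyNA(x$zcta_id)) x <- x[!is.na(zcta_id)]
  out <- x[, .(value = sum(value * wgt)), by = .(zcta_id, date)]
  data.table::setnames(out, "value", value_name)
  data.table::setorder(out, zcta_id, date)
  out[]
}

#' Build the ZCTA-day exposure series
#'
#' Population-weights gridded Tmax and wildfire-influenced PM2.5 to the
#' ZCTA level and merges them into one series.
#'
#' @param tmax Gridded daily Tmax (degF).
#' @param wf_pm25 Gridded daily wildfire-influenced PM2.5.
#' @param crosswalk Cell-to-ZCTA crosswalk.
#' @return data.table (zcta_id, date, tmax, wf_pm25).
#' @export
build_exposure_series <- function(tmax, wf_pm25, crosswalk) {
  a <- population_weighted_zcta(tmax, crosswalk, "tmax")
  b <- population_weighted_zcta(wf_pm25, crosswalk, "wf_pm25")
  out <- a[b, on = c("zcta_id", "date")]
  data.table::setorder(out, zcta_id, date)
  out[]
}

#' Month- and ZCTA-specific extreme-heat thresholds
#'
#' Empirical percentiles (linear interpolation between order statistics)
#' of daily maximum temperature pooled across all study years, computed
#' separately per (ZCTA, calendar month).
#'
#' @param series Exposure series with zcta_id, date, tmax.
#' @param percentiles Percentile levels, default c(90, 95, 99).
#' @param min_obs Minimum observations required per (ZCTA, month) pool.
#' @return data.table (zcta_id, month, percentile, threshold_F).
#' @export
heat_thresholds <- function(series, percentiles = c(90, 95, 99),
                            min_obs = 28L) {
  series <- data.table::as.data.table(series)
  stopifnot_cols(series, c("zcta_id", "date", "tmax"), "series")
  s <- data.table::copy(series)[, month := data.table::month(date)]
  cnt <- s[, .N, by = .(zcta_id, month)]
  if (any(cnt$N < min_obs)) {
    bad <- cnt[N < min_obs]
    hs_stop("heatsmoke_input_error",
            "fewer than %d Tmax observations for: %s", min_obs,
            paste(sprintf("(%s, month %d)", bad$zcta_id, bad$month),
                  collapse = ", "))
  }
  out <- s[, {
    q <- quantile(tmax, probs = percentiles / 100, type = 7, names = FALSE)
    list(percentile = percentiles, threshold_F = q)
  }, by = .(zcta_id, month)]
  data.table::setorder(out, zcta_id, month, percentile)
  out[]
}

#' Flag extreme-heat days
#'
#' A day is an extreme-heat day when its ZCTA-level Tmax is strictly
#' greater than the month- and ZCTA-specific threshold at the chosen
#' percentile.
#'
#' @param series Exposure series (zcta_id, date, tmax, ...).
#' @param thresholds Output of [heat_thresholds()].
#' @param percentile Threshold percentile to apply (90, 95 or 99).
#' @return The series with a logical `heat_day` column added.
#' @export
flag_extreme_heat <- function(series, thresholds, percentile = 95) {
  series <- data.table::as.data.table(series)
  thresholds <- data.table::as.data.table(thresholds)
  pct <- percentile
  th <- thresholds[thresholds[["percentile"]] == pct]
  if (!nrow(th)) {
    hs_stop("heatsmoke_input_error",
            "no thresholds at percentile %s", percentile)
  }
  out <- data.table::copy(series)[, month := data.table::month(date)]
  out <- th[, .(zcta_id, month, threshold_F)][out, on = c("zcta_id", "month")]
  if (anyNA(out$threshold_F)) {
    bad <- unique(out[is.na(threshold_F), .(zcta_id, month)])
    hs_stop("heatsmoke_input_error", "missing threshold for: %s",
            paste(sprintf("(%s, %d)", bad$zcta_id, bad$month), collapse = ", "))
  }
  out[, heat_day := tmax > threshold_F]
  out[, c("threshold_F", "month") := NULL]
  data.table::setcolorder(out, names(series))
  data.table::setorder(out, zcta_id, date)
  out[]
}
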