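# Independent oracles used across tests. These deliberately avoid the
# package's own computational path: direct enumeration, hand-rolled
# arithmetic, central differences.

# Conditional log-likelihood by direct enumeration: for each stratum,
# the probability that the observed case day is the case among all
# candidate days, computed as a plain ratio of exponentiated scores.
oracle_loglik <- function(beta, design) {
  ll <- 0
  for (sid in unique(design$stratum_id)) {
    d <- design[design$stratum_id == sid, ]
    w <- exp(beta[1] * d$x_heat + beta[2] * d$x_smoke +
               beta[3] * d$x_heat * d$x_smoke)
    ll <- ll + log(w[d$is_case] / sum(w))
  }
  ll
}

# Central-difference gradient of a scalar function.
numeric_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(k) {
    e <- rep(0, length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Random small strata (2-6 rows, one case) for oracle-equivalence checks.
random_small_strata <- function(n_strata, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_strata), function(i) {
    m <- sample(2:6, 1)
    xh <- rbinom(m, 1, 0.4)
    xs <- ifelse(runif(m) < 0.5, round(rexp(m, 1 / 3), 3), 0)
    data.frame(stratum_id = i, is_case = seq_len(m) == sample.int(m, 1),
               x_heat = as.numeric(xh), x_smoke = xs)
  })
  data.table::rbindlist(rows)
}

# A tiny fully-specified gridded environment for exposure tests:
# `values` is a list of per-cell daily vectors keyed by cell_id.
make_field <- function(values, dates, nx = NULL, ny = NULL) {
  out <- data.table::rbindlist(lapply(names(values), function(cid) {
    data.table::data.table(cell_id = as.integer(cid), date = dates,
                           value = values[[cid]])
  }))
  data.table::setorder(out, cell_id, date)
  if (!is.null(nx)) data.table::setattr(out, "nx", nx)
  if (!is.null(ny)) data.table::setattr(out, "ny", ny)
  out
}

make_plumes <- function(field, plume_dates_by_cell = list()) {
  out <- field[, c("cell_id", "date")]
  out[, plume_present := FALSE]
  for (cid in names(plume_dates_by_cell)) {
    out[cell_id == as.integer(cid) &
          date %in% plume_dates_by_cell[[cid]], plume_present := TRUE]
  }
  out[]
}

# Small default simulation for pipeline-level tests.
small_sim_config <- function(...) {
  simulation_config(n_cells_x = 6L, n_cells_y = 6L, n_zctas = 4L,
                    date_start = as.Date("2015-01-01"),
                    date_end = as.Date("2016-12-31"), ...)
}

# Generator + exposure pipeline in one call.
small_pipeline <- function(cfg) {
  env <- generate_environment(cfg)
  base <- smoke_free_baseline(env$pm25, env$plumes)
  wf <- wf_influenced_pm25(env$pm25, env$plumes, base)
  series <- build_exposure_series(env$tmax, wf, env$crosswalk)
  th <- heat_thresholds(series)
  list(env = env, baseline = base, wf = wf, thresholds = th,
       series = flag_extreme_heat(series, th, cfg$heat_percentile))
}
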