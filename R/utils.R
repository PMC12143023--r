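#' @import data.table
#' @importFrom stats quantile rnorm rlnorm rpois rbinom rexp runif pnorm qnorm rmultinom
NULL

# Internal: stop with a classed condition so callers can test error types.
hs_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "heatsmoke_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Internal: run `expr` under a temporary RNG seed, restoring prior RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Internal: day-of-year key on a fixed 365-day calendar; Feb 29 pools with
# Feb 28 so "same day of year" is well-defined across leap years.
month_day_key <- function(dates) {
  m <- data.table::month(dates)
  d <- data.table::mday(dates)
  d[m == 2L & d == 29L] <- 28L
  cum <- cumsum(c(0L, c(31L, 28L, 31L, 30L, 31L, 30L,
                        31L, 31L, 30L, 31L, 30L, 31L)))[1:12]
  cum[m] + d
}

# Internal: circular distance between day-of-year keys on the 365-day wheel.
doy_circ_dist <- function(a, b) {
  d <- abs(a - b)
  pmin(d, 365L - d)
}

stopifnot_cols <- function(dt, cols, what) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    hs_stop("heatsmoke_input_error", "%s is missing column(s): %s",
            what, paste(miss, collapse = ", "))
  }
}
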