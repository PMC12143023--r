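# Multiplicative and additive interaction measures from a fitted
# conditional logistic interaction model.
#
# With heat a binary indicator and smoke a continuous exposure, odds
# ratios are defined against the doubly-unexposed at a smoke increment
# delta (micrograms/m^3):
#   OR01 = exp(bH)                      heat alone
#   OR10 = exp(bS * delta)              smoke alone
#   OR11 = exp(bH + bS*delta + bHS*delta)  joint exposure
#   multiplicative interaction = OR11 / (OR01 * OR10) = exp(bHS * delta)
#   RERI = OR11 - OR10 - OR01 + 1       relative excess risk, additive scale
#   AP   = RERI / OR11                  attributable proportion
# Confidence intervals for RERI and AP use the delta method: the
# measure's gradient in (bH, bS, bHS) propagated through the fit
# covariance; the multiplicative measure and single-exposure ORs use Wald
# intervals on the log scale.

#' Interaction measures with delta-method confidence intervals
#'
#' @param fit A converged [fit_clogit()] result.
#' @param delta Smoke exposure increment defining the contrasts,
#'   micrograms/m^3 (1 by default; joint and smoke-alone odds ratios are
#'   "per delta").
#' @param conf_level Confidence level for all intervals.
#' @return Object of class `hs_interaction`: a list with `delta`,
#'   `conf_level`, a one-row data.table `estimates` holding every measure
#'   with its CI and two-sided normal p-value (`*_p`; halve for the
#'   one-sided convention, reported as `*_p1`), and the input fit.
#' @export
interaction_measures <- function(fit, delta = 1, conf_level = 0.95) {
  stopifnot(inherits(fit, "hs_fit"))
  if (!fit$converged) {
    hs_stop("heatsmoke_fit_error",
            "refusing to compute interaction measures from a non-converged fit (%s)",
            fit$diagnostic)
  }
  stopifnot(delta > 0, conf_level > 0, conf_level < 1)
  b <- fit$beta
  V <- fit$covariance
  z <- qnorm(1 - (1 - conf_level) / 2)

  bH <- b[["beta_H"]]; bS <- b[["beta_S"]]; bHS <- b[["beta_HS"]]
  or01 <- exp(bH)
  or10 <- exp(bS * delta)
  or11 <- exp(bH + bS * delta + bHS * delta)
  mult <- exp(bHS * delta)
  reri <- or11 - or10 - or01 + 1
  ap <- reri / or11

  # Wald on the log scale for ORs and the multiplicative measure
  lincomb <- function(a) {
    est <- sum(a * b)
    se <- sqrt(drop(t(a) %*% V %*% a))
    c(exp(est), exp(est - z * se), exp(est + z * se),
      2 * pnorm(-abs(est / se)))
  }
  m01 <- lincomb(c(1, 0, 0))
  m10 <- lincomb(c(0, delta, 0))
  m11 <- lincomb(c(1, delta, delta))
  mm  <- lincomb(c(0, 0, delta))

  # delta method for RERI: gradient in (bH, bS, bHS)
  g_reri <- c(or11 - or01, delta * (or11 - or10), delta * or11)
  se_reri <- sqrt(drop(t(g_reri) %*% V %*% g_reri))

  # delta method for AP, directly on AP's own gradient
  g_ap <- c((or11 - or01) / or11 - ap,
            delta * ((or11 - or10) / or11 - ap),
            delta * (1 - ap))
  se_ap <- sqrt(drop(t(g_ap) %*% V %*% g_ap))

  est <- data.table::data.table(
    or01 = m01[1], or01_lo = m01[2], or01_hi = m01[3], or01_p = m01[4],
    or10 = m10[1], or10_lo = m10[2], or10_hi = m10[3], or10_p = m10[4],
    or11 = m11[1], or11_lo = m11[2], or11_hi = m11[3], or11_p = m11[4],
    mult = mm[1], mult_lo = mm[2], mult_hi = mm[3], mult_p = mm[4],
    reri = reri, reri_se = se_reri,
    reri_lo = reri - z * se_reri, reri_hi = reri + z * se_reri,
    reri_p = 2 * pnorm(-abs(reri / se_reri)),
    ap = ap, ap_se = se_ap,
    ap_lo = ap - z * se_ap, ap_hi = ap + z * se_ap,
    ap_p = 2 * pnorm(-abs(ap / se_ap)),
    ap_p1 = pnorm(-abs(ap / se_ap)),
    delta = delta
  )
  structure(list(estimates = est, delta = delta, conf_level = conf_level,
                 p_value_convention = "two-sided normal ('_p1' one-sided)",
                 fit = fit),
            class = "hs_interaction")
}

#' @export
print.hs_interaction <- function(x, ...) {
  e <- x$estimates
  fmt <- function(v, lo, hi, p) {
    sprintf("%7.4f  [%7.4f, %7.4f]  p=%.4g", v, lo, hi, p)
  }
  cat(sprintf("Interaction measures (smoke increment delta = %g ug/m3, %g%% CI)\n",
              x$delta, 100 * x$conf_level))
  cat(" OR01 (heat alone):  ", fmt(e$or01, e$or01_lo, e$or01_hi, e$or01_p), "\n")
  cat(" OR10 (smoke alone): ", fmt(e$or10, e$or10_lo, e$or10_hi, e$or10_p), "\n")
  cat(" OR11 (joint):       ", fmt(e$or11, e$or11_lo, e$or11_hi, e$or11_p), "\n")
  cat(" multiplicative:     ", fmt(e$mult, e$mult_lo, e$mult_hi, e$mult_p), "\n")
  cat(" RERI:               ", fmt(e$reri, e$reri_lo, e$reri_hi, e$reri_p), "\n")
  cat(" AP:                 ", fmt(e$ap, e$ap_lo, e$ap_hi, e$ap_p), "\n")
  cat(" p-values:", x$p_value_convention, "\n")
  invisible(x)
}
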