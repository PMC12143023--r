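# Exact conditional likelihood for 1:M matched case-crossover strata and
# its Newton-Raphson maximizer.
#
# Within stratum j with rows r and linear predictor eta_r, the
# conditional probability that the observed case day is the case is
# exp(eta_case) / sum_r exp(eta_r); stratum intercepts cancel. The model
# has three terms: heat indicator, smoke exposure, and their product.

# Internal: design matrix and compacted stratum index from a design table.
design_parts <- function(design) {
  design <- data.table::as.data.table(design)
  stopifnot_cols(design, c("stratum_id", "is_case", "x_heat", "x_smoke"),
                 "design")
  s <- match(design$stratum_id, unique(design$stratum_id))
  o <- order(s)
  if (is.unsorted(s)) {
    design <- design[o]
    s <- s[o]
  }
  ncase <- rowsum(as.numeric(design$is_case), s, reorder = FALSE)[, 1]
  if (any(ncase != 1)) {
    hs_stop("heatsmoke_design_error",
            "every stratum must contain exactly one case row (%d violate)",
            sum(ncase != 1))
  }
  X <- cbind(heat = design$x_heat, smoke = design$x_smoke,
             interaction = design$x_heat * design$x_smoke)
  list(X = X, s = s, case = design$is_case, n_strata = max(s))
}

#' Conditional log-likelihood, gradient and Hessian
#'
#' Evaluates the exact conditional log-likelihood of the matched-set
#' logistic model at `beta = (beta_H, beta_S, beta_HS)` over all strata,
#' with analytic gradient and Hessian. Strata whose rows all share the
#' same (heat, smoke) exposure contribute a constant `log(1/m)` and zero
#' gradient.
#'
#' @param beta Numeric length-3 coefficient vector.
#' @param design Long design table (stratum_id, is_case, x_heat, x_smoke),
#'   one case row per stratum.
#' @return List: `loglik` (scalar), `gradient` (length 3), `hessian`
#'   (3 x 3, negative semidefinite).
#' @export
conditional_loglik <- function(beta, design) {
  p <- design_parts(design)
  cl_core(beta, p)
}

# Internal core on precomputed parts (used by the Newton loop).
cl_core <- function(beta, p) {
  eta <- as.vector(p$X %*% beta)
  gm <- data.table::data.table(s = p$s, eta = eta)[
    , max(eta), by = s][["V1"]]
  w <- exp(eta - gm[p$s])
  denom <- rowsum(w, p$s, reorder = FALSE)[, 1]
  pr <- w / denom[p$s]
  loglik <- sum(eta[p$case]) - sum(gm + log(denom))
  Ex <- rowsum(pr * p$X, p$s, reorder = FALSE)      # n_strata x 3, E_j[x]
  gradient <- colSums(p$X[p$case, , drop = FALSE]) - colSums(Ex)
  Exx <- crossprod(p$X, pr * p$X)                    # sum_j E_j[x x']
  hessian <- -(Exx - crossprod(Ex))
  dimnames(hessian) <- list(colnames(p$X), colnames(p$X))
  names(gradient) <- colnames(p$X)
  list(loglik = loglik, gradient = gradient, hessian = hessian)
}

#' Fit the conditional logistic interaction model
#'
#' Newton-Raphson maximization of the exact conditional likelihood with
#' step-halving, started at `beta = 0`. Convergence is declared when the
#' largest absolute score falls below `gtol` or the relative
#' log-likelihood change falls below `lltol`. Non-informative strata
#' (identical exposures on every day) are dropped and counted. Monotone
#' likelihoods (complete or quasi-complete separation) are flagged as
#' non-converged with a diagnostic rather than silently diverging.
#'
#' @param design Long design table (stratum_id, is_case, x_heat, x_smoke).
#' @param max_iter Maximum Newton iterations.
#' @param gtol Gradient convergence tolerance.
#' @param lltol Relative log-likelihood change tolerance.
#' @return An object of class `hs_fit`: `beta` (named length-3),
#'   `covariance` (inverse observed information), `loglik`, `converged`,
#'   `n_strata_used`, `n_strata_dropped_noninformative`, `n_iter`,
#'   `diagnostic`.
#' @export
fit_clogit <- function(design, max_iter = 50L, gtol = 1e-8, lltol = 1e-10) {
  design <- data.table::as.data.table(design)
  stopifnot_cols(design, c("stratum_id", "is_case", "x_heat", "x_smoke"),
                 "design")

  # drop non-informative strata: no within-stratum exposure contrast
  info <- design[, .(informative = data.table::uniqueN(paste(x_heat, x_smoke)) > 1L),
                 by = stratum_id]
  n_drop <- sum(!info$informative)
  keep <- info$stratum_id[info$informative]
  if (!length(keep)) {
    hs_stop("heatsmoke_design_error",
            "no informative stratum: all exposures are constant within strata")
  }
  d <- design[stratum_id %in% keep]
  p <- design_parts(d)

  # a term with no within-stratum variation anywhere is conditionally
  # inestimable (singular information)
  for (k in seq_len(ncol(p$X))) {
    varies <- rowsum(p$X[, k], p$s, reorder = FALSE)[, 1] /
      tabulate(p$s)
    dev <- p$X[, k] - varies[p$s]
    if (all(abs(dev) < 1e-12)) {
      hs_stop("heatsmoke_design_error",
              "term '%s' has no within-stratum variation (singular information)",
              colnames(p$X)[k])
    }
  }

  beta <- c(0, 0, 0)
  ev <- cl_core(beta, p)
  converged <- FALSE
  diagnostic <- NA_character_
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(-ev$hessian, ev$gradient), error = function(e) NULL)
    if (is.null(step)) {
      diagnostic <- "singular Hessian during iteration"
      break
    }
    tt <- 1
    repeat {
      cand <- beta + tt * step
      ev2 <- cl_core(cand, p)
      if (is.finite(ev2$loglik) && ev2$loglik >= ev$loglik - 1e-12) break
      tt <- tt / 2
      if (tt < 1e-8) break
    }
    rel <- abs(ev2$loglik - ev$loglik) / (abs(ev$loglik) + 1e-12)
    beta <- beta + tt * step
    ev <- ev2
    if (max(abs(ev$gradient)) < gtol || rel < lltol) {
      converged <- max(abs(ev$gradient)) < gtol || rel < lltol
      break
    }
    if (max(abs(beta)) > 15) {
      diagnostic <- paste("possible separation (monotone likelihood):",
                          "coefficient escaping to +/-infinity")
      break
    }
  }
  if (!converged && is.na(diagnostic)) diagnostic <- "max_iter reached"

  covariance <- tryCatch(solve(-ev$hessian), error = function(e) {
    matrix(NA_real_, 3, 3, dimnames = dimnames(ev$hessian))
  })
  if (converged && anyNA(covariance)) {
    converged <- FALSE
    diagnostic <- "singular information at optimum"
  }
  names(beta) <- c("beta_H", "beta_S", "beta_HS")
  structure(list(
    beta = beta, covariance = covariance, loglik = ev$loglik,
    gradient = ev$gradient, converged = converged, n_iter = iter,
    n_strata_used = p$n_strata,
    n_strata_dropped_noninformative = n_drop,
    diagnostic = diagnostic
  ), class = "hs_fit")
}

#' @export
print.hs_fit <- function(x, ...) {
  cat("Conditional logistic interaction fit\n")
  se <- sqrt(diag(x$covariance))
  tab <- data.frame(estimate = x$beta, se = se,
                    z = x$beta / se,
                    p = 2 * pnorm(-abs(x$beta / se)))
  print(round(tab, 5))
  cat(sprintf("loglik %.4f | %d strata (%d non-informative dropped) | %s\n",
              x$loglik, x$n_strata_used,
              x$n_strata_dropped_noninformative,
              if (x$converged) sprintf("converged in %d iterations", x$n_iter)
              else paste("NOT converged:", x$diagnostic)))
  invisible(x)
}
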