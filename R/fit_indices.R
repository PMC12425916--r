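#' Root-mean-square error of approximation
#'
#' `sqrt(max(chi2 - df, 0) / (df * n))`: per-degree-of-freedom misfit, zero
#' whenever the chi-square does not exceed its degrees of freedom.
#'
#' @param chi2 Model chi-square.
#' @param df Degrees of freedom (> 0).
#' @param n Sample size.
#' @return The point RMSEA.
#' @export
rmsea <- function(chi2, df, n) {
  stopifnot(df > 0, n > 0, chi2 >= 0)
  sqrt(max(chi2 - df, 0) / (df * n))
}

#' Noncentral confidence interval for the RMSEA
#'
#' Inverts the noncentral chi-square distribution: the bounds are
#' `sqrt(lambda / (df * n))` for the noncentrality values at which the
#' observed statistic sits at the `(1 + level)/2` and `(1 - level)/2`
#' quantiles, floored at zero.
#'
#' @inheritParams rmsea
#' @param level Confidence level, default 0.90.
#' @return Numeric vector `c(lower, upper)`.
#' @export
rmsea_ci <- function(chi2, df, n, level = 0.90) {
  stopifnot(df > 0, n > 0, chi2 >= 0, level > 0, level < 1)
  solve_ncp <- function(target_p) {
    # find lambda with pchisq(chi2, df, ncp = lambda) == target_p
    if (pchisq(chi2, df) < target_p) return(0)
    upper <- max(chi2 * 2, df * 2, 10)
    while (pchisq(chi2, df, ncp = upper) > target_p) {
      upper <- upper * 2
      if (upper > 1e8) stop("RMSEA interval: noncentrality search diverged", call. = FALSE)
    }
    uniroot(function(l) pchisq(chi2, df, ncp = l) - target_p,
            c(0, upper), tol = 1e-10)$root
  }
  lo <- solve_ncp((1 + level) / 2)
  hi <- solve_ncp((1 - level) / 2)
  sqrt(c(lo, hi) / (df * n))
}

#' Fit indices for a fitted structural model
#'
#' Computes the chi-square p-value, CFI, TLI, RMSEA with its 90% interval, and
#' SRMR. CFI and TLI compare the model to the independence baseline
#' ([baseline_chi2()]); both are truncated at 1. For a saturated model
#' (`df = 0`) the RMSEA and TLI are undefined and reported as `NA`.
#'
#' SRMR is the root mean square of the standardized residuals
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)` over the `p(p+1)/2` unique elements,
#' diagonal included (set `include_diagonal = FALSE` for the off-diagonal
#' dialect).
#'
#' @param fit A [fit_ml()] result.
#' @param baseline Optional list `(chi2, df)` from [baseline_chi2()]; computed
#'   from `s` when omitted.
#' @param s Sample covariance matrix; defaults to the one stored in `fit`.
#' @param include_diagonal Logical, SRMR convention (see Details).
#' @return Object of class `fit_indices` with fields `chi2`, `df`, `p_value`,
#'   `cfi`, `tli`, `rmsea`, `rmsea_ci90`, `srmr`.
#' @export
fit_indices <- function(fit, baseline = NULL, s = NULL, include_diagonal = TRUE) {
  stopifnot(inherits(fit, "sem_fit"))
  s <- s %||% fit$s
  if (is.null(baseline)) baseline <- baseline_chi2(s, fit$n, fit$multiplier)
  if (baseline$df < fit$df) stop("baseline df must be >= model df", call. = FALSE)
  chi2 <- fit$chi2; df <- fit$df; n <- fit$n

  excess <- max(chi2 - df, 0)
  denom <- max(baseline$chi2 - baseline$df, excess, 0)
  cfi <- if (denom > 0) 1 - excess / denom else 1

  if (df > 0) {
    rb <- baseline$chi2 / baseline$df
    tli <- if (abs(rb - 1) > 0) min(((rb) - (chi2 / df)) / (rb - 1), 1) else 1
    rm <- rmsea(chi2, df, n)
    rci <- rmsea_ci(chi2, df, n)
    p_value <- pchisq(chi2, df, lower.tail = FALSE)
  } else {
    tli <- NA_real_; rm <- NA_real_; rci <- c(NA_real_, NA_real_); p_value <- NA_real_
  }

  d <- sqrt(diag(s))
  resid <- (s - fit$sigma_hat) / outer(d, d)
  keep <- if (include_diagonal) lower.tri(resid, diag = TRUE) else lower.tri(resid)
  srmr <- sqrt(mean(resid[keep]^2))

  structure(list(chi2 = chi2, df = df, p_value = p_value, cfi = cfi, tli = tli,
                 rmsea = rm, rmsea_ci90 = rci, srmr = srmr),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2 = %.2f (df = %d, p = %s), CFI = %.3f, TLI = %s, RMSEA = %s [%s; %s], SRMR = %.3f\n",
              x$chi2, x$df, ifelse(is.na(x$p_value), "NA", sprintf("%.3f", x$p_value)),
              x$cfi, ifelse(is.na(x$tli), "NA", sprintf("%.3f", x$tli)),
              ifelse(is.na(x$rmsea), "NA", sprintf("%.3f", x$rmsea)),
              ifelse(is.na(x$rmsea_ci90[1]), "NA", sprintf("%.3f", x$rmsea_ci90[1])),
              ifelse(is.na(x$rmsea_ci90[2]), "NA", sprintf("%.3f", x$rmsea_ci90[2])),
              x$srmr))
  invisible(x)
}
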