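#' Closed-form standardized cross-lagged effect
#'
#' The standardized effect of X1 on Y2 adjusting for Y1, as a function of the
#' three correlations alone:
#' \deqn{\beta = \frac{r_{X_1 Y_2} - r_{X_1 Y_1}\, r_{Y_1 Y_2}}{1 - r_{X_1 Y_1}^2}.}
#' This is the focal path of the cross-lagged panel model and the oracle
#' against which the fitted CLPM is checked.
#'
#' @param r_xy2 Correlation of the predictor with the wave-2 outcome.
#' @param r_xy1 Correlation of the predictor with the wave-1 outcome.
#' @param r_y1y2 Outcome stability correlation.
#' @return The standardized regression coefficient.
#' @export
beta_lagged <- function(r_xy2, r_xy1, r_y1y2) {
  if (any(abs(r_xy1) >= 1)) {
    stop("degenerate collinearity: |r_xy1| must be < 1", call. = FALSE)
  }
  (r_xy2 - r_xy1 * r_y1y2) / (1 - r_xy1^2)
}

#' Closed-form standardized difference-score effect
#'
#' The effect of X1 on the (standardized) Y2 - Y1 difference score:
#' \deqn{\beta = \frac{r_{X_1 Y_2} - r_{X_1 Y_1}}{\sqrt{2(1 - r_{Y_1 Y_2})}}.}
#' Equals the standardized focal effect of the latent change score model
#' built by [build_lcsm()].
#'
#' @inheritParams beta_lagged
#' @export
beta_change <- function(r_xy2, r_xy1, r_y1y2) {
  if (any(r_y1y2 >= 1)) {
    stop("zero-variance change: r_y1y2 must be < 1", call. = FALSE)
  }
  (r_xy2 - r_xy1) / sqrt(2 * (1 - r_y1y2))
}

#' Closed-form time-reversed cross-lagged effect
#'
#' The effect of the wave-1 predictor on the wave-1 outcome adjusting for the
#' wave-2 outcome — [beta_lagged()] with the roles of the two outcome waves
#' exchanged. Under a genuine prospective effect this coefficient is expected
#' to carry the opposite sign of the forward cross-lagged effect.
#'
#' @param r_pe1 Correlation of the predictor with the wave-1 outcome.
#' @param r_pe2 Correlation of the predictor with the wave-2 outcome.
#' @param r_e1e2 Outcome stability correlation.
#' @export
beta_reversed <- function(r_pe1, r_pe2, r_e1e2) {
  if (any(abs(r_pe2) >= 1)) {
    stop("degenerate collinearity: |r_pe2| must be < 1", call. = FALSE)
  }
  (r_pe1 - r_pe2 * r_e1e2) / (1 - r_pe2^2)
}

# --- builders ----------------------------------------------------------------

empty_ram <- function(vars) {
  v <- length(vars)
  list(Af = matrix(0, v, v, dimnames = list(vars, vars)),
       Al = matrix(NA_character_, v, v, dimnames = list(vars, vars)),
       Sf = matrix(0, v, v, dimnames = list(vars, vars)),
       Sl = matrix(NA_character_, v, v, dimnames = list(vars, vars)))
}

#' Cross-lagged panel model (model A)
#'
#' Two-wave CLPM over the observed variables (P1, P2, E1, E2): E2 and P2 are
#' each regressed on both wave-1 variables, the wave-1 variables covary, and
#' the wave-2 residuals covary. The model is saturated (10 free parameters,
#' df = 0); the focal effect is the path P1 -> E2.
#'
#' @return A [sem_spec()].
#' @export
build_clpm <- function() {
  vars <- PANEL_VARS
  r <- empty_ram(vars)
  r$Al["E2", "P1"] <- "b_pe"   # focal cross-lagged path
  r$Al["E2", "E1"] <- "s_e"
  r$Al["P2", "P1"] <- "s_p"
  r$Al["P2", "E1"] <- "b_ep"
  diag(r$Sl) <- c("v_p1", "v_p2", "v_e1", "v_e2")
  r$Sl["P1", "E1"] <- r$Sl["E1", "P1"] <- "c_w1"
  r$Sl["P2", "E2"] <- r$Sl["E2", "P2"] <- "c_w2"
  start_fn <- function(s) {
    x <- c("P1", "E1")
    bE <- solve(s[x, x], s[x, "E2"])
    bP <- solve(s[x, x], s[x, "P2"])
    ve <- s["E2", "E2"] - sum(bE * s[x, "E2"])
    vp <- s["P2", "P2"] - sum(bP * s[x, "P2"])
    cw2 <- s["P2", "E2"] - sum(bP * s[x, "E2"]) - sum(bE * s[x, "P2"]) +
      sum(bP * (s[x, x] %*% bE))
    c(b_pe = unname(bE["P1"]), s_e = unname(bE["E1"]),
      s_p = unname(bP["P1"]), b_ep = unname(bP["E1"]),
      v_p1 = s["P1", "P1"], v_e1 = s["E1", "E1"],
      v_p2 = max(vp, 1e-6), v_e2 = max(ve, 1e-6),
      c_w1 = s["P1", "E1"], c_w2 = cw2)
  }
  sem_spec(vars, vars, r$Af, r$Al, r$Sf, r$Sl, focal = "b_pe",
           focal_from = "P1", focal_to = "E2", name = "clpm",
           start_fn = start_fn)
}

#' Time-reversed cross-lagged panel model (model B)
#'
#' Regresses the wave-1 outcome on the wave-2 outcome and the wave-1
#' predictor, over the three observed variables (P1, E1, E2) — the regression
#' named by the time-reversal logic; P2 plays no role. Saturated (6 free
#' parameters, df = 0); focal effect is the path P1 -> E1.
#'
#' @return A [sem_spec()].
#' @export
build_reversed_clpm <- function() {
  vars <- c("P1", "E1", "E2")
  r <- empty_ram(vars)
  r$Al["E1", "P1"] <- "b_rev"  # focal reversed path
  r$Al["E1", "E2"] <- "s_rev"
  diag(r$Sl) <- c("v_p1", "v_e1", "v_e2")
  r$Sl["P1", "E2"] <- r$Sl["E2", "P1"] <- "c_p1e2"
  start_fn <- function(s) {
    x <- c("P1", "E2")
    b <- solve(s[x, x], s[x, "E1"])
    c(b_rev = unname(b["P1"]), s_rev = unname(b["E2"]),
      v_p1 = s["P1", "P1"], v_e2 = s["E2", "E2"],
      v_e1 = max(s["E1", "E1"] - sum(b * s[x, "E1"]), 1e-6),
      c_p1e2 = s["P1", "E2"])
  }
  sem_spec(vars, vars, r$Af, r$Al, r$Sf, r$Sl, focal = "b_rev",
           focal_from = "P1", focal_to = "E1", name = "reversed_clpm",
           start_fn = start_fn)
}

#' Latent change score model (model C)
#'
#' Defines latent change variables via fixed unit loadings,
#' `E2 = 1*E1 + 1*dE` and `P2 = 1*P1 + 1*dP` with zero wave-2 residuals, and
#' regresses each change on the other construct's wave-1 score (dE <- P1,
#' dP <- E1). Each change disturbance covaries freely with its construct's
#' own wave-1 score and with the other change disturbance, so the model stays
#' saturated (10 free parameters, df = 0). There is no proportional-change
#' regression of dE on E1; under this parameterization the standardized focal
#' effect P1 -> dE equals the difference-score coefficient [beta_change()]
#' exactly.
#'
#' @return A [sem_spec()].
#' @export
build_lcsm <- function() {
  vars <- c(PANEL_VARS, "dP", "dE")
  r <- empty_ram(vars)
  r$Af["P2", "P1"] <- 1
  r$Af["P2", "dP"] <- 1
  r$Af["E2", "E1"] <- 1
  r$Af["E2", "dE"] <- 1
  r$Al["dE", "P1"] <- "b_dE"   # focal: predictor -> latent change in outcome
  r$Al["dP", "E1"] <- "b_dP"
  diag(r$Sl) <- c("v_p1", NA, "v_e1", NA, "v_dP", "v_dE")  # P2/E2 residuals fixed 0
  r$Sl["P1", "E1"] <- r$Sl["E1", "P1"] <- "c_w1"
  r$Sl["dE", "E1"] <- r$Sl["E1", "dE"] <- "c_dE_e1"
  r$Sl["dP", "P1"] <- r$Sl["P1", "dP"] <- "c_dP_p1"
  r$Sl["dP", "dE"] <- r$Sl["dE", "dP"] <- "c_dd"
  start_fn <- function(s) {
    # moment-matched solution: dE = E2 - E1, dP = P2 - P1
    cde <- s[, "E2"] - s[, "E1"]   # cov(col, dE)
    cdp <- s[, "P2"] - s[, "P1"]
    vde <- s["E2", "E2"] + s["E1", "E1"] - 2 * s["E1", "E2"]
    vdp <- s["P2", "P2"] + s["P1", "P1"] - 2 * s["P1", "P2"]
    b_dE <- cde[["P1"]] / s["P1", "P1"]
    b_dP <- cdp[["E1"]] / s["E1", "E1"]
    # disturbances u_E = dE - b_dE P1, u_P = dP - b_dP E1
    c(b_dE = b_dE, b_dP = b_dP,
      v_p1 = s["P1", "P1"], v_e1 = s["E1", "E1"],
      v_dE = max(vde - b_dE^2 * s["P1", "P1"], 1e-6),
      v_dP = max(vdp - b_dP^2 * s["E1", "E1"], 1e-6),
      c_w1 = s["P1", "E1"],
      c_dE_e1 = cde[["E1"]] - b_dE * s["P1", "E1"],
      c_dP_p1 = cdp[["P1"]] - b_dP * s["P1", "E1"],
      c_dd = (s["P2", "E2"] - s["P2", "E1"] - s["P1", "E2"] + s["P1", "E1"]) -
        b_dE * cdp[["P1"]] - b_dP * cde[["E1"]] + b_dE * b_dP * s["P1", "E1"])
  }
  sem_spec(vars, PANEL_VARS, r$Af, r$Al, r$Sf, r$Sl, focal = "b_dE",
           focal_from = "P1", focal_to = "dE", name = "lcsm",
           start_fn = start_fn)
}

#' Artifactualness model (model D)
#'
#' A second-order common-factor model with no direct predictor-outcome paths:
#' P1 and P2 load (fixed 1) on a latent general predictor factor gP, E1 and E2
#' on a general outcome factor gE, and both first-order factors load on a
#' second-order "general negativity" factor gNeg — gP with loading 1, gE with
#' loading `sign` (+1 or -1 according to the sign of the predictor-outcome
#' correlations). Same-occasion observed scores share one state covariance.
#' Free parameters (4): var(gNeg), a common indicator residual variance for
#' P1/P2, one for E1/E2, and the same-occasion state covariance; first-order
#' factor disturbances are fixed to 0, giving df = 6. A good fit signals that
#' the observed cross-lagged pattern could have arisen without any direct
#' effects.
#'
#' @param sign +1 or -1: the sign of the predictor-outcome correlations.
#' @return A [sem_spec()].
#' @export
build_artifact_model <- function(sign = 1) {
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1", call. = FALSE)
  vars <- c(PANEL_VARS, "gP", "gE", "gNeg")
  r <- empty_ram(vars)
  r$Af["P1", "gP"] <- 1
  r$Af["P2", "gP"] <- 1
  r$Af["E1", "gE"] <- 1
  r$Af["E2", "gE"] <- 1
  r$Af["gP", "gNeg"] <- 1
  r$Af["gE", "gNeg"] <- sign
  diag(r$Sl) <- c("theta_p", "theta_p", "theta_e", "theta_e", NA, NA, "v_gneg")
  r$Sl["P1", "E1"] <- r$Sl["E1", "P1"] <- "state_cov"
  r$Sl["P2", "E2"] <- r$Sl["E2", "P2"] <- "state_cov"
  start_fn <- function(s) {
    v <- max((s["P1", "P2"] + s["E1", "E2"]) / 2, 0.02)
    c(v_gneg = v,
      theta_p = max(mean(c(s["P1", "P1"], s["P2", "P2"])) - v, 0.05),
      theta_e = max(mean(c(s["E1", "E1"], s["E2", "E2"])) - v, 0.05),
      state_cov = (s["P1", "E1"] + s["P2", "E2"]) / 2 - sign * v)
  }
  sem_spec(vars, PANEL_VARS, r$Af, r$Al, r$Sf, r$Sl,
           name = if (sign > 0) "artifact(+)" else "artifact(-)",
           start_fn = start_fn)
}

# --- focal effect extraction -------------------------------------------------

#' Extract and standardize the focal effect of a fitted model
#'
#' Pulls the focal path coefficient from a converged [fit_ml()] result and
#' standardizes it using the fitted model's own implied variances
#' (`b_std = b * sd(from) / sd(to)`, latent variances included), so exact-mode
#' and stochastic-mode data share one code path. The standard error is
#' propagated by the delta method over all free parameters; the 95% interval
#' and two-sided p-value are Wald-based.
#'
#' @param fit A converged [fit_ml()] result whose spec declares a focal path.
#' @param model Label attached to the estimate: `"clpm"`, `"reversed"`, or
#'   `"lcsm"`.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return An `effect_estimate`: `b` (standardized), `se`, `ci95`, `p_value`,
#'   `significant`.
#' @export
focal_effect <- function(fit, model = c("clpm", "reversed", "lcsm"), alpha = 0.05) {
  model <- match.arg(model)
  stopifnot(inherits(fit, "sem_fit"))
  if (!isTRUE(fit$converged)) {
    stop(sprintf("refusing to extract a focal effect from a non-converged fit of '%s' (max gradient %.3g)",
                 fit$spec$name, fit$grad_norm), call. = FALSE)
  }
  spec <- fit$spec
  if (is.null(spec$focal)) stop(sprintf("model '%s' has no focal path", spec$name), call. = FALSE)
  std <- function(theta) {
    sig <- implied_full(spec, theta)
    i <- match(spec$focal_from, spec$variables)
    j <- match(spec$focal_to, spec$variables)
    theta[[spec$focal]] * sqrt(sig[i, i] / sig[j, j])
  }
  b <- std(fit$theta)
  # delta method: numeric gradient of the standardized coefficient
  g <- vapply(seq_along(fit$theta), function(k) {
    h <- 1e-6 * max(1, abs(fit$theta[k]))
    up <- dn <- fit$theta
    up[k] <- up[k] + h
    dn[k] <- dn[k] - h
    (std(up) - std(dn)) / (2 * h)
  }, numeric(1))
  se <- sqrt(max(drop(t(g) %*% fit$vcov %*% g), 0))
  z <- if (se > 0) b / se else 0
  p <- if (se > 0) 2 * pnorm(-abs(z)) else as.numeric(b == 0)
  ci <- b + c(-1, 1) * qnorm(0.975) * se
  structure(list(model = model, b = b, se = se, ci95 = ci, p_value = p,
                 significant = p < alpha),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s focal effect: %s\n", x$model,
              format_effect_cell(x$b, x$ci95[1], x$ci95[2], x$p_value)))
  invisible(x)
}
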