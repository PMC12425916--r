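#' Normal-theory maximum-likelihood discrepancy
#'
#' \eqn{F(\Sigma, S) = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p},
#' the fit function whose minimum over the free parameters, scaled by the
#' sample size, gives the model chi-square. `F` is zero iff `sigma == s`.
#'
#' @param sigma Model-implied covariance matrix (positive definite).
#' @param s Sample covariance matrix of the same order.
#' @return The discrepancy value (non-negative at a minimum).
#' @export
ml_discrepancy <- function(sigma, s) {
  stopifnot(is.matrix(sigma), is.matrix(s), all(dim(sigma) == dim(s)))
  ci <- chol_info(sigma)
  if (is.null(ci)) stop_not_pd("sigma")
  cs <- chol_info(s)
  if (is.null(cs)) stop_not_pd("s")
  ci$logdet + sum(s * ci$inv) - cs$logdet - nrow(s)
}

# --- internal engine ---------------------------------------------------------

# Evaluate F, its analytic gradient, and the building blocks for the expected
# information at a parameter point. RAM algebra:
#   B = (I-A)^-1, M = B S B', Sigma = M[obs, obs]
#   dF/dtheta = tr(W dSigma),  W = Sigma^-1 - Sigma^-1 S_samp Sigma^-1
# dSigma for a path entry (i,j) of A is C + C' with C = outer(B[,i], M[j,]);
# for an S entry (i,j) it is B[,i] B[,j]' (+ transpose off-diagonal).
sem_eval <- function(spec, theta, s, obs_idx, want_grad = TRUE) {
  m <- theta_matrices(spec, theta)
  v <- length(spec$variables)
  B <- tryCatch(solve(diag(v) - m$A), error = function(e) NULL)
  if (is.null(B)) return(list(ok = FALSE))
  M <- B %*% m$S %*% t(B)
  Sigma <- M[obs_idx, obs_idx, drop = FALSE]
  ci <- chol_info(Sigma)
  if (is.null(ci)) return(list(ok = FALSE))
  p <- length(obs_idx)
  Fval <- ci$logdet + sum(s * ci$inv) - attr(s, "logdet") - p
  out <- list(ok = TRUE, F = Fval, B = B, M = M, Sigma = Sigma, Sinv = ci$inv)
  if (!want_grad) return(out)
  W <- ci$inv - ci$inv %*% s %*% ci$inv
  Bo <- B[obs_idx, , drop = FALSE]
  Mo <- M[, obs_idx, drop = FALSE]
  WBo <- W %*% Bo
  g <- vapply(spec$labels, function(lab) {
    pos <- spec$positions[[lab]]
    gi <- 0
    if (nrow(pos$A)) for (r in seq_len(nrow(pos$A))) {
      i <- pos$A[r, 1]; j <- pos$A[r, 2]
      gi <- gi + 2 * sum(Mo[j, ] * WBo[, i])
    }
    if (nrow(pos$S)) for (r in seq_len(nrow(pos$S))) {
      i <- pos$S[r, 1]; j <- pos$S[r, 2]
      gi <- gi + if (i == j) sum(Bo[, i] * WBo[, i]) else 2 * sum(Bo[, j] * WBo[, i])
    }
    gi
  }, numeric(1))
  out$grad <- g
  out
}

# Partial derivatives dSigma/dtheta_k as explicit p x p matrices.
sem_dsigma <- function(spec, ev, obs_idx) {
  Bo <- ev$B[obs_idx, , drop = FALSE]
  Mo <- ev$M[, obs_idx, drop = FALSE]
  lapply(spec$labels, function(lab) {
    pos <- spec$positions[[lab]]
    d <- matrix(0, length(obs_idx), length(obs_idx))
    if (nrow(pos$A)) for (r in seq_len(nrow(pos$A))) {
      C <- outer(Bo[, pos$A[r, 1]], Mo[pos$A[r, 2], ])
      d <- d + C + t(C)
    }
    if (nrow(pos$S)) for (r in seq_len(nrow(pos$S))) {
      i <- pos$S[r, 1]; j <- pos$S[r, 2]
      C <- outer(Bo[, i], Bo[, j])
      d <- d + if (i == j) C else C + t(C)
    }
    d
  })
}

# Hessian approximation H_jk = tr(Sinv dSig_j Sinv dSig_k); the expected
# information on the chi-square scale is (multiplier/2) * H.
sem_hessian <- function(ev, dsig) {
  k <- length(dsig)
  Ts <- lapply(dsig, function(d) ev$Sinv %*% d)
  H <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    H[i, j] <- H[j, i] <- sum(Ts[[i]] * t(Ts[[j]]))
  }
  H
}

#' Fit a structural model by maximum likelihood
#'
#' Minimizes the [ml_discrepancy()] between the model-implied and the sample
#' covariance matrix over the free parameters of a [sem_spec()]. Optimization
#' uses quasi-Newton (BFGS) iterations with analytic gradients, followed by
#' Fisher-scoring polish steps; variance parameters are log-transformed during
#' iteration so the implied matrix stays positive definite. Convergence is
#' declared when the maximum absolute (unscaled) parameter change between
#' iterations falls below `tol_param` (default 0.0001) or the gradient norm
#' falls below `tol_grad`; non-convergence is flagged, never silently accepted.
#'
#' Standard errors come from the inverse of the expected information at the
#' optimum. The chi-square statistic is `multiplier * F_min` with
#' `multiplier = n` by default (`"n-1"` is available; the two are
#' indistinguishable at the sample sizes this package targets).
#'
#' @param spec A [sem_spec()].
#' @param s Sample covariance matrix over (at least) `spec$observed`; when it
#'   carries dimnames the observed block is selected by name.
#' @param n Sample size.
#' @param start Optional named start values overriding the defaults
#'   (0.1 for paths and covariances, half the mean observed variance for
#'   variance parameters).
#' @param multiplier `"n"` (default) or `"n-1"`: the chi-square scaling.
#' @param max_iter Iteration cap for the quasi-Newton stage.
#' @param tol_param,tol_grad Convergence tolerances (see Details).
#' @return An object of class `sem_fit`: parameter estimates `theta`, standard
#'   errors `se`, covariance `vcov` of the estimates, implied matrix
#'   `sigma_hat`, `chi2`, `df`, `n`, `converged`, `n_iter`.
#' @export
fit_ml <- function(spec, s, n, start = NULL, multiplier = c("n", "n-1"),
                   max_iter = 1000L, tol_param = 1e-4, tol_grad = 1e-8) {
  multiplier <- match.arg(multiplier)
  stopifnot(inherits(spec, "sem_spec"), n >= 4)
  if (!is.null(dimnames(s))) {
    if (!all(spec$observed %in% rownames(s))) {
      stop(sprintf("sample covariance lacks variables: %s",
                   paste(setdiff(spec$observed, rownames(s)), collapse = ", ")),
           call. = FALSE)
    }
    s <- s[spec$observed, spec$observed]
  }
  p <- length(spec$observed)
  stopifnot(all(dim(s) == p))
  cs <- chol_info(s)
  if (is.null(cs)) stop_not_pd("sample covariance")
  attr(s, "logdet") <- cs$logdet
  obs_idx <- match(spec$observed, spec$variables)

  labels <- spec$labels
  k <- length(labels)
  islog <- labels %in% spec$variance_labels

  theta0 <- setNames(ifelse(islog, 0.5 * mean(diag(s)), 0.1), labels)
  for (src in list(spec$start, start)) {
    if (!is.null(src)) {
      src <- src[names(src) %in% labels]
      theta0[names(src)] <- src
    }
  }
  theta0[islog] <- pmax(theta0[islog], 1e-8)

  to_eta <- function(th) {
    eta <- th
    eta[islog] <- log(th[islog])
    eta
  }
  from_eta <- function(eta) {
    th <- eta
    th[islog] <- exp(eta[islog])
    setNames(th, labels)
  }

  f_only <- function(eta) {
    ev <- sem_eval(spec, from_eta(eta), s, obs_idx, want_grad = FALSE)
    if (!ev$ok) 1e10 else ev$F
  }
  g_eta <- function(eta) {
    th <- from_eta(eta)
    ev <- sem_eval(spec, th, s, obs_idx)
    if (!ev$ok) return(rep(0, k))
    ev$grad * ifelse(islog, th, 1)
  }

  eta <- to_eta(theta0)
  if (f_only(eta) >= 1e9) {
    # fallback start: observed variances, null paths
    theta0 <- setNames(ifelse(islog, mean(diag(s)), 0), labels)
    eta <- to_eta(theta0)
    if (f_only(eta) >= 1e9) {
      stop(sprintf("no feasible start values found for model '%s'", spec$name), call. = FALSE)
    }
  }

  opt <- optim(eta, f_only, g_eta, method = "BFGS",
               control = list(maxit = max_iter, reltol = 1e-12))
  eta <- opt$par
  n_iter <- unname(opt$counts[1])

  # Fisher-scoring polish towards the stated convergence criterion
  d_max <- Inf
  for (it in seq_len(60L)) {
    th <- from_eta(eta)
    ev <- sem_eval(spec, th, s, obs_idx)
    if (!ev$ok) break
    scale <- ifelse(islog, th, 1)
    g <- ev$grad * scale
    if (max(abs(ev$grad)) < 1e-12) { d_max <- 0; break }
    H <- sem_hessian(ev, sem_dsigma(spec, ev, obs_idx))
    He <- H * outer(scale, scale)
    step <- tryCatch(solve(He + 1e-10 * max(diag(He), 1) * diag(k), -g),
                     error = function(e) NULL)
    if (is.null(step)) break
    f_cur <- ev$F
    lam <- 1
    repeat {
      eta_new <- eta + lam * step
      if (f_only(eta_new) <= f_cur + 1e-14) break
      lam <- lam / 2
      if (lam < 1e-10) { eta_new <- eta; break }
    }
    d_max <- max(abs(from_eta(eta_new) - th))
    eta <- eta_new
    n_iter <- n_iter + 1L
    if (d_max < 1e-11) break
  }

  theta <- from_eta(eta)
  ev <- sem_eval(spec, theta, s, obs_idx)
  if (!ev$ok) stop(sprintf("fit of model '%s' left the feasible region", spec$name), call. = FALSE)
  grad_norm <- max(abs(ev$grad))
  converged <- (d_max < tol_param) || (grad_norm < tol_grad)
  if (!converged) {
    warning(sprintf("model '%s' did not converge (max parameter change %.2g, gradient %.2g)",
                    spec$name, d_max, grad_norm), call. = FALSE)
  }

  mult <- if (multiplier == "n") n else n - 1
  chi2 <- max(mult * ev$F, 0)
  df <- p * (p + 1) / 2 - k

  dsig <- sem_dsigma(spec, ev, obs_idx)
  H <- sem_hessian(ev, dsig)
  evals <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(evals) <= max(evals) * 1e-10) {
    stop(sprintf("model '%s' is not identified: rank-deficient information matrix", spec$name),
         call. = FALSE)
  }
  vcov <- solve((mult / 2) * H)
  dimnames(vcov) <- list(labels, labels)

  structure(list(
    spec = spec, theta = theta, se = sqrt(diag(vcov)), vcov = vcov,
    sigma_hat = structure(ev$Sigma, dimnames = list(spec$observed, spec$observed)),
    s = s, chi2 = chi2, df = df, n = n, multiplier = multiplier,
    F_min = ev$F, converged = converged, n_iter = n_iter, grad_norm = grad_norm
  ), class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf("sem_fit '%s': chi2 = %.4g (df = %d, n = %d), %s after %d iterations\n",
              x$spec$name, x$chi2, x$df, x$n,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  est <- data.frame(estimate = x$theta, se = x$se)
  print(round(est, 4))
  invisible(x)
}

#' Independence-baseline chi-square
#'
#' Fits the independence model (free variances, all covariances fixed to zero)
#' needed as the baseline of incremental fit indices. Its maximum-likelihood
#' solution is analytic — the fitted variances equal the sample variances — so
#' the statistic reduces to `-multiplier * log|R|` with `R` the sample
#' correlation matrix; `df = p(p-1)/2`.
#'
#' @inheritParams fit_ml
#' @return List with `chi2` and `df`.
#' @export
baseline_chi2 <- function(s, n, multiplier = c("n", "n-1")) {
  multiplier <- match.arg(multiplier)
  cs <- chol_info(as.matrix(s))
  if (is.null(cs)) stop_not_pd("s")
  p <- nrow(s)
  mult <- if (multiplier == "n") n else n - 1
  logdet_R <- cs$logdet - sum(log(diag(s)))
  list(chi2 = max(-mult * logdet_R, 0), df = p * (p - 1) / 2)
}
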