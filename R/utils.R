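# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# ML (denominator n) sample covariance; what the discrepancy function is
# evaluated against so that chi2 = n * F_min is internally consistent.
cov_ml <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2L, colMeans(x))
  crossprod(xc) / nrow(x)
}

# log-determinant and inverse through Cholesky; returns NULL when the matrix
# is not (numerically) positive definite.
chol_info <- function(m) {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  list(logdet = 2 * sum(log(diag(ch))), inv = chol2inv(ch))
}

stop_not_pd <- function(what) {
  stop(sprintf("matrix '%s' is not positive definite", what), call. = FALSE)
}

# Significance stars: * p<0.05, ** p<0.01, *** p<0.001.
p_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

fmt2 <- function(x) ifelse(is.na(x), "", sprintf("%.2f", x))

# "0.35 [0.28; 0.42]**" — the cell layout used for focal effects.
format_effect_cell <- function(b, lo, hi, p) {
  sprintf("%.2f [%.2f; %.2f]%s", b, lo, hi, p_stars(p))
}
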