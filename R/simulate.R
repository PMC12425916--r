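#' Validate a 4x4 panel correlation matrix
#'
#' Checks the repo-wide two-wave layout — variables ordered (P1, P2, E1, E2) —
#' for unit diagonal, symmetry, and positive semidefiniteness.
#'
#' @param m A 4x4 numeric matrix.
#' @return The matrix with dimnames set, classed `corr4`.
#' @export
correlation_matrix4 <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 4L), is.numeric(m))
  if (max(abs(m - t(m))) > 1e-12) stop("correlation matrix must be symmetric", call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-12) stop("correlation matrix must have unit diagonal", call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf("correlation matrix is not positive semidefinite (smallest eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  }
  dimnames(m) <- list(PANEL_VARS, PANEL_VARS)
  structure(m, class = c("corr4", "matrix"))
}

#' Assemble the correlation matrix of a study record
#'
#' Places the six pairwise correlations of a study record into the 4x4 matrix
#' over (P1, P2, E1, E2) and validates positive semidefiniteness.
#'
#' @param record A single study record (one row of a [load_studies()] /
#'   [builtin_table1()] data frame, or a list with the six `r_*` fields).
#' @return A `corr4` matrix.
#' @export
correlation_matrix <- function(record) {
  fields <- c("r_p1p2", "r_p1e1", "r_p1e2", "r_p2e1", "r_p2e2", "r_e1e2")
  vals <- vapply(fields, function(f) as.numeric(record[[f]][1]), numeric(1))
  if (anyNA(vals)) {
    stop(sprintf("record %s is missing correlations: %s",
                 record[["effect_id"]][1] %||% "?",
                 paste(fields[is.na(vals)], collapse = ", ")), call. = FALSE)
  }
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- vals[["r_p1p2"]]
  m[1, 3] <- m[3, 1] <- vals[["r_p1e1"]]
  m[1, 4] <- m[4, 1] <- vals[["r_p1e2"]]
  m[2, 3] <- m[3, 2] <- vals[["r_p2e1"]]
  m[2, 4] <- m[4, 2] <- vals[["r_p2e2"]]
  m[3, 4] <- m[4, 3] <- vals[["r_e1e2"]]
  correlation_matrix4(m)
}

#' Simulate standardized two-wave panel data
#'
#' Draws `n` observations of (P1, P2, E1, E2) from a zero-mean multivariate
#' normal with the target correlation matrix as covariance. In `"exact"` mode
#' (the default throughout the package) the draws are re-centered, whitened by
#' the sample factor and re-colored by the target factor, so the sample
#' correlation matrix equals the target exactly and every column has mean 0
#' and SD 1; standardized estimates then become deterministic functions of the
#' target matrix. `"stochastic"` mode returns plain i.i.d. draws.
#'
#' @param target A `corr4` target correlation matrix (or any PSD covariance
#'   matrix with unit diagonal).
#' @param n Number of observations (> 4; exact-mode whitening is undefined at
#'   or below the number of variables).
#' @param mode `"exact"` or `"stochastic"`.
#' @param seed Optional integer seed; the draw is reproducible given
#'   `(target, n, seed)`.
#' @return A `panel_dataset`: list with `scores` (n x 4 matrix, columns
#'   P1, P2, E1, E2), `mode`, `seed`, `target`.
#' @export
sample_mvn <- function(target, n, mode = c("exact", "stochastic"), seed = NULL) {
  mode <- match.arg(mode)
  if (!inherits(target, "corr4")) target <- correlation_matrix4(as.matrix(target))
  if (n <= 4) stop("n must exceed the number of variables (4)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  scores <- MASS::mvrnorm(n, mu = rep(0, 4), Sigma = unclass(target),
                          empirical = (mode == "exact"))
  colnames(scores) <- PANEL_VARS
  structure(list(scores = scores, mode = mode, seed = seed, target = target),
            class = "panel_dataset")
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat(sprintf("panel_dataset: n = %d, mode = %s%s\n", nrow(x$scores), x$mode,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Sample correlation matrix of a panel dataset
#'
#' @param data A `panel_dataset` from [sample_mvn()] or an n x 4 score matrix.
#' @return The Pearson correlation matrix of the columns, as `corr4`.
#' @export
sample_correlations <- function(data) {
  scores <- if (inherits(data, "panel_dataset")) data$scores else as.matrix(data)
  if (nrow(scores) < 4) stop("at least 4 observations are required", call. = FALSE)
  sds <- apply(scores, 2, sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate data: zero-variance column(s) %s",
                 paste(colnames(scores)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  correlation_matrix4(unname(cor(scores)))
}

#' Write panel scores as CSV
#'
#' Header `P1,P2,E1,E2`, one row per observation.
#'
#' @param data A `panel_dataset` or score matrix.
#' @param path Output file path.
#' @export
write_dataset <- function(data, path) {
  scores <- if (inherits(data, "panel_dataset")) data$scores else as.matrix(data)
  write.csv(as.data.frame(scores), path, row.names = FALSE)
  invisible(path)
}
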