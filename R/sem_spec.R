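#' Structural model specifications in RAM form
#'
#' A `sem_spec` describes a structural equation model by the RAM
#' (reticular action model) matrices: a square matrix `A` of directed paths, a
#' symmetric matrix `S` of variances and covariances (of exogenous variables
#' and disturbances), and the selection of observed variables. Every entry of
#' `A` and `S` is either fixed to a numeric value or assigned a free-parameter
#' label; the same label in several cells imposes an equality constraint. The
#' model-implied covariance matrix of the observed variables is
#' \deqn{\Sigma(\theta) = F (I - A)^{-1} S (I - A)^{-\top} F^\top,}
#' where `F` selects the observed rows.
#'
#' Only recursive (acyclic) path structures are accepted, which covers the
#' four panel models built by [build_clpm()], [build_reversed_clpm()],
#' [build_lcsm()] and [build_artifact_model()].
#'
#' @param variables Character vector naming all variables, observed and latent.
#' @param observed Character vector, subset of `variables`: the observed ones.
#' @param A_fixed,A_label Square numeric / character matrices over `variables`.
#'   `A_label[i, j]` is `NA` where the path j -> i is fixed (at `A_fixed[i, j]`)
#'   and a parameter label where it is free.
#' @param S_fixed,S_label Same layout for the symmetric (co)variance matrix.
#' @param start Optional named numeric vector of user start values per label.
#' @param focal Label of the focal path (the scrutinized effect), or `NULL`.
#' @param focal_from,focal_to Variable names spanning the focal path; used to
#'   standardize the focal coefficient from the implied covariance matrix.
#' @param name Short model name used in printing and error messages.
#' @param start_fn Optional function of the sample covariance matrix returning
#'   named start values (used for fast moment-based initialization).
#'
#' @return An object of class `sem_spec`.
#' @seealso [fit_ml()], [model_implied_sigma()], [spec_to_json()]
#' @export
sem_spec <- function(variables, observed, A_fixed, A_label, S_fixed, S_label,
                     start = NULL, focal = NULL, focal_from = NULL,
                     focal_to = NULL, name = "sem", start_fn = NULL) {
  v <- length(variables)
  stopifnot(is.character(variables), v >= 1, all(observed %in% variables))
  for (m in list(A_fixed, S_fixed)) stopifnot(is.matrix(m), dim(m) == c(v, v))
  for (m in list(A_label, S_label)) stopifnot(is.matrix(m), dim(m) == c(v, v))
  dimnames(A_fixed) <- dimnames(A_label) <- dimnames(S_fixed) <-
    dimnames(S_label) <- list(variables, variables)
  # S must be pattern-symmetric
  if (!isTRUE(all.equal(S_fixed, t(S_fixed))) ||
      !identical(is.na(S_label), is.na(t(S_label))) ||
      any(S_label != t(S_label), na.rm = TRUE)) {
    stop("S pattern must be symmetric (values and labels)", call. = FALSE)
  }
  # recursive-only check: the directed-path pattern must be acyclic
  adj <- (A_fixed != 0) | !is.na(A_label)
  reach <- adj
  for (k in seq_len(v)) reach <- (reach %*% adj > 0) | reach
  if (any(diag(reach) > 0)) {
    stop(sprintf("model '%s' has a cyclic path structure; only recursive models are supported", name),
         call. = FALSE)
  }

  # free parameters in a stable order: A entries column-major, then the lower
  # triangle (incl. diagonal) of S
  a_idx <- which(!is.na(A_label), arr.ind = TRUE)
  s_all <- which(!is.na(S_label), arr.ind = TRUE)
  s_idx <- s_all[s_all[, 1] >= s_all[, 2], , drop = FALSE]
  labels <- unique(c(A_label[a_idx], S_label[s_idx]))
  positions <- lapply(labels, function(lab) {
    list(A = a_idx[A_label[a_idx] == lab, , drop = FALSE],
         S = s_idx[S_label[s_idx] == lab, , drop = FALSE])
  })
  names(positions) <- labels
  variance_labels <- unique(na.omit(diag(S_label)))

  structure(list(
    variables = variables, observed = observed,
    A_fixed = A_fixed, A_label = A_label,
    S_fixed = S_fixed, S_label = S_label,
    labels = labels, positions = positions,
    variance_labels = variance_labels,
    start = start, start_fn = start_fn,
    focal = focal, focal_from = focal_from, focal_to = focal_to,
    name = name
  ), class = "sem_spec")
}

#' @export
print.sem_spec <- function(x, ...) {
  p <- length(x$observed)
  cat(sprintf("sem_spec '%s': %d variables (%d observed), %d free parameters, df = %d\n",
              x$name, length(x$variables), p, length(x$labels),
              p * (p + 1) / 2 - length(x$labels)))
  cat(sem_equations(x), sep = "\n")
  invisible(x)
}

# Fill the RAM matrices at a parameter point.
theta_matrices <- function(spec, theta) {
  A <- spec$A_fixed
  S <- spec$S_fixed
  for (lab in spec$labels) {
    pos <- spec$positions[[lab]]
    if (nrow(pos$A)) A[pos$A] <- theta[[lab]]
    if (nrow(pos$S)) {
      S[pos$S] <- theta[[lab]]
      S[pos$S[, c(2, 1), drop = FALSE]] <- theta[[lab]]
    }
  }
  list(A = A, S = S)
}

# Implied covariance over ALL variables (latents included).
implied_full <- function(spec, theta) {
  m <- theta_matrices(spec, theta)
  v <- length(spec$variables)
  B <- tryCatch(solve(diag(v) - m$A), error = function(e) NULL)
  if (is.null(B)) {
    stop(sprintf("(I - A) is singular for model '%s'", spec$name), call. = FALSE)
  }
  B %*% m$S %*% t(B)
}

#' Model-implied covariance matrix
#'
#' Evaluates \eqn{F (I-A)^{-1} S (I-A)^{-\top} F^\top} at a parameter point:
#' the covariance matrix of the observed variables implied by a [sem_spec()].
#'
#' @param spec A [sem_spec()].
#' @param theta Named numeric vector assigning every free-parameter label.
#' @return A symmetric covariance matrix over `spec$observed`.
#' @export
model_implied_sigma <- function(spec, theta) {
  theta <- theta[spec$labels]
  if (anyNA(theta)) {
    stop(sprintf("theta must assign every free label of '%s'", spec$name), call. = FALSE)
  }
  implied_full(spec, theta)[spec$observed, spec$observed]
}

#' Render a model specification as equations
#'
#' One line per regression (`~`), (co)variance (`~~`) with `fix(value)` /
#' `free(label)` coefficients — a human-readable audit of the RAM pattern.
#'
#' @param spec A [sem_spec()].
#' @return Character vector of equation lines.
#' @export
sem_equations <- function(spec) {
  v <- spec$variables
  out <- character(0)
  coef_str <- function(fix, lab) if (is.na(lab)) sprintf("fix(%g)", fix) else sprintf("free(%s)", lab)
  for (i in seq_along(v)) {
    on <- which(spec$A_fixed[i, ] != 0 | !is.na(spec$A_label[i, ]))
    if (length(on)) {
      terms <- vapply(on, function(j) {
        paste0(coef_str(spec$A_fixed[i, j], spec$A_label[i, j]), "*", v[j])
      }, character(1))
      out <- c(out, paste(v[i], "~", paste(terms, collapse = " + ")))
    }
  }
  for (i in seq_along(v)) for (j in seq_len(i)) {
    if (spec$S_fixed[i, j] != 0 || !is.na(spec$S_label[i, j])) {
      out <- c(out, paste(v[i], "~~",
                          paste0(coef_str(spec$S_fixed[i, j], spec$S_label[i, j]), "*", v[j])))
    }
  }
  out
}

#' Serialize a model specification to JSON
#'
#' Matrices are written with `"fix:<value>"` / `"free:<label>"` entries so that
#' fitted models are auditable and alternative parameterizations can be
#' supplied without code changes. [spec_from_json()] inverts the encoding.
#'
#' @param spec A [sem_spec()].
#' @param path Optional file path; when given the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
spec_to_json <- function(spec, path = NULL) {
  enc <- function(fix, lab) {
    m <- matrix(sprintf("fix:%.17g", fix), nrow(fix), dimnames = dimnames(fix))
    m[!is.na(lab)] <- paste0("free:", lab[!is.na(lab)])
    m
  }
  obj <- list(
    name = spec$name, variables = spec$variables, observed = spec$observed,
    A = enc(spec$A_fixed, spec$A_label), S = enc(spec$S_fixed, spec$S_label),
    start = as.list(spec$start %||% setNames(list(), character(0))),
    focal = spec$focal, focal_from = spec$focal_from, focal_to = spec$focal_to
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname spec_to_json
#' @param json A JSON string or path to a JSON file produced by [spec_to_json()].
#' @export
spec_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  dec <- function(m) {
    m <- as.matrix(m)
    fix <- matrix(0, nrow(m), ncol(m))
    lab <- matrix(NA_character_, nrow(m), ncol(m))
    isf <- startsWith(m, "fix:")
    fix[isf] <- as.numeric(substring(m[isf], 5L))
    lab[!isf] <- sub("^free:", "", m[!isf])
    list(fix = fix, lab = lab)
  }
  A <- dec(obj$A); S <- dec(obj$S)
  start <- if (length(obj$start)) unlist(obj$start) else NULL
  sem_spec(obj$variables, obj$observed, A$fix, A$lab, S$fix, S$lab,
           start = start, focal = obj$focal %||% NULL,
           focal_from = obj$focal_from %||% NULL,
           focal_to = obj$focal_to %||% NULL, name = obj$name)
}
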