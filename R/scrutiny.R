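#' Verdict rule configuration
#'
#' Thresholds for the sign-convergence verdict: the significance level for
#' focal effects and the CFI above which the artifactualness model counts as
#' well fitting (the conventional 0.95 cut; an RMSEA cut is carried for
#' reporting). The underlying reasoning is qualitative — the defaults
#' operationalize it and every threshold is configurable.
#'
#' @param alpha Two-sided significance level, default 0.05.
#' @param cfi_good CFI threshold for a "good" artifactualness fit, default 0.95.
#' @param rmsea_good RMSEA threshold carried in reports, default 0.06.
#' @return A `verdict_config` list.
#' @export
verdict_config <- function(alpha = 0.05, cfi_good = 0.95, rmsea_good = 0.06) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, cfi_good = cfi_good, rmsea_good = rmsea_good),
            class = "verdict_config")
}

#' Classify a scrutiny pattern
#'
#' Encodes the three expectations a genuine prospective effect must meet and
#' their artifactual mirror image:
#' * `consistent_with_genuine` — the CLPM focal effect A is significant, the
#'   time-reversed effect B has the opposite sign, and the latent-change
#'   effect C is significant with the same sign as A.
#' * `artifactual_pattern` — A is significant, B has the SAME sign as A
#'   (contradicting time-reversal logic), C is non-significant or
#'   opposite-signed, and the artifactualness model fits well
#'   (CFI >= `config$cfi_good`).
#' * `inconclusive` — anything else, including hedged cases where the
#'   reversed effect is non-significant and C shares A's sign without
#'   reaching significance.
#'
#' @param a,b,c `effect_estimate`s for the CLPM, reversed CLPM, and LCSM.
#' @param d `fit_indices` of the artifactualness model.
#' @param config A [verdict_config()].
#' @return One of `"consistent_with_genuine"`, `"artifactual_pattern"`,
#'   `"inconclusive"`.
#' @export
classify_pattern <- function(a, b, c, d, config = verdict_config()) {
  sgn <- function(x) sign(x)
  a_sig <- isTRUE(a$p_value < config$alpha)
  c_sig <- isTRUE(c$p_value < config$alpha)
  if (a_sig && sgn(b$b) == -sgn(a$b) && c_sig && sgn(c$b) == sgn(a$b)) {
    return("consistent_with_genuine")
  }
  if (a_sig && sgn(b$b) == sgn(a$b) && (!c_sig || sgn(c$b) == -sgn(a$b)) &&
      isTRUE(d$cfi >= config$cfi_good)) {
    return("artifactual_pattern")
  }
  "inconclusive"
}

# Core of the pipeline, shared by scrutinize_study() and the recovery
# experiments: fit models A-D to one dataset and classify.
scrutinize_scores <- function(scores, n, config, effect_id = "synthetic",
                              multiplier = "n", notes = "") {
  s <- cov_ml(scores)
  # numerically-zero cross-correlations carry no sign information
  r_w1 <- s["P1", "E1"] / sqrt(s["P1", "P1"] * s["E1", "E1"])
  r_w2 <- s["P2", "E2"] / sqrt(s["P2", "P2"] * s["E2", "E2"])
  sign_w1 <- if (abs(r_w1) < 1e-8) 0 else sign(r_w1)
  sign_w2 <- if (abs(r_w2) < 1e-8) 0 else sign(r_w2)
  if (sign_w1 != 0 && sign_w2 != 0 && sign_w1 != sign_w2) {
    warning(sprintf("effect %s: wave-1 and wave-2 cross-correlations disagree in sign; using wave 1",
                    effect_id), call. = FALSE)
    notes <- paste(notes, "cross-correlation signs disagree across waves;")
  }
  d_sign <- if (sign_w1 < 0) -1 else 1

  fit1 <- function(spec) fit_ml(spec, s, n, start = spec$start_fn(s), multiplier = multiplier)
  fa <- fit1(build_clpm())
  fb <- fit1(build_reversed_clpm())
  fc <- fit1(build_lcsm())
  fd <- fit1(build_artifact_model(d_sign))

  ea <- focal_effect(fa, "clpm", alpha = config$alpha)
  eb <- focal_effect(fb, "reversed", alpha = config$alpha)
  ec <- focal_effect(fc, "lcsm", alpha = config$alpha)
  id <- fit_indices(fd)

  structure(list(
    effect_id = effect_id, effect_A = ea, effect_B = eb, effect_C = ec,
    fit_D = id, verdict = classify_pattern(ea, eb, ec, id, config),
    notes = trimws(notes),
    fits = list(A = fa, B = fb, C = fc, D = fd)
  ), class = "scrutiny_result")
}

#' Scrutinize one study record
#'
#' Runs the full four-model scrutiny for a single study: assembles the 4x4
#' correlation matrix from the record's six correlations, simulates `n`
#' standardized observations ([sample_mvn()]), fits the CLPM, the reversed
#' CLPM, the latent change score model, and the artifactualness model (its
#' sign taken from the sign of `r_p1e1`), extracts the focal effects and fit
#' indices, and classifies the pattern ([classify_pattern()]).
#'
#' @param record One study record with all six correlations present.
#' @param mode `"exact"` (default; results are a deterministic function of the
#'   correlations) or `"stochastic"`.
#' @param seed Integer seed for the simulation draw.
#' @param config A [verdict_config()].
#' @return A `scrutiny_result`: the three `effect_estimate`s, the
#'   artifactualness `fit_indices`, the verdict, and the underlying fits.
#' @export
scrutinize_study <- function(record, mode = c("exact", "stochastic"), seed = 1L,
                             config = verdict_config()) {
  mode <- match.arg(mode)
  if (is.data.frame(record) && nrow(record) != 1) {
    stop("scrutinize_study expects a single record; see scrutinize_all()", call. = FALSE)
  }
  effect_id <- as.character(record[["effect_id"]][1] %||% "?")
  target <- correlation_matrix(record)
  n <- as.integer(record[["n"]][1])
  if (n < 50) {
    warning(sprintf("effect %s: n = %d is small; fitted models may be unstable", effect_id, n),
            call. = FALSE)
  }
  data <- sample_mvn(target, n, mode, seed)
  res <- tryCatch(
    scrutinize_scores(data$scores, n, config, effect_id = effect_id),
    error = function(e) {
      stop(sprintf("effect %s: %s", effect_id, conditionMessage(e)), call. = FALSE)
    })
  res$mode <- mode
  res$seed <- seed
  res
}

#' @export
print.scrutiny_result <- function(x, ...) {
  cell <- function(e) format_effect_cell(e$b, e$ci95[1], e$ci95[2], e$p_value)
  cat(sprintf("scrutiny of effect %s: %s\n", x$effect_id, x$verdict))
  cat(sprintf("  A (CLPM)      %s\n", cell(x$effect_A)))
  cat(sprintf("  B (reversed)  %s\n", cell(x$effect_B)))
  cat(sprintf("  C (LCSM)      %s\n", cell(x$effect_C)))
  cat(sprintf("  D (artifact)  chi2 = %.1f, CFI = %.2f, RMSEA = %s [%s; %s]\n",
              x$fit_D$chi2, x$fit_D$cfi, fmt2(x$fit_D$rmsea),
              fmt2(x$fit_D$rmsea_ci90[1]), fmt2(x$fit_D$rmsea_ci90[2])))
  if (nzchar(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

#' Scrutinize a collection of study records
#'
#' Applies [scrutinize_study()] to every record, in input order, with
#' per-record seeds derived from `seed`. Per-record failures (e.g., missing
#' correlations) are collected as `scrutiny_error` entries rather than
#' aborting the batch; a verdict tally is reported via `message()`.
#'
#' @param records Validated study records.
#' @param mode,seed,config As in [scrutinize_study()].
#' @return A list with one `scrutiny_result` (or `scrutiny_error`) per record.
#' @export
scrutinize_all <- function(records, mode = c("exact", "stochastic"), seed = 1L,
                           config = verdict_config()) {
  mode <- match.arg(mode)
  if (is.null(records) || nrow(records) == 0) {
    warning("empty study collection; nothing to scrutinize", call. = FALSE)
    return(list())
  }
  results <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    results[[i]] <- tryCatch(
      scrutinize_study(records[i, ], mode, seed + i - 1L, config),
      error = function(e) {
        structure(list(effect_id = as.character(records$effect_id[i]),
                       error = conditionMessage(e)),
                  class = "scrutiny_error")
      })
  }
  ok <- Filter(function(r) inherits(r, "scrutiny_result"), results)
  tally <- table(factor(vapply(ok, `[[`, "", "verdict"),
                        levels = c("consistent_with_genuine", "artifactual_pattern",
                                   "inconclusive")))
  message(sprintf("scrutinized %d/%d effects: %s", length(ok), nrow(records),
                  paste(names(tally), tally, sep = " = ", collapse = ", ")))
  results
}
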