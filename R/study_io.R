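# Study records: one row per reanalyzed cross-lagged effect. Correlation
# columns follow the repo-wide (P1, P2, E1, E2) order convention.
STUDY_COLS <- c("effect_id", "n", "r_p1p2", "r_p1e1", "r_p1e2", "r_p2e1",
                "r_p2e2", "r_e1e2", "predictor_name", "waves", "original_b",
                "pct_male", "mean_age")
CORR_COLS <- c("r_p1p2", "r_p1e1", "r_p1e2", "r_p2e1", "r_p2e2", "r_e1e2")

validate_studies <- function(df) {
  missing_cols <- setdiff(c("effect_id", "n"), names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: missing required field(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(STUDY_COLS, names(df))) df[[col]] <- NA
  df <- df[, STUDY_COLS]
  df$effect_id <- as.character(df$effect_id)
  df$predictor_name <- as.character(df$predictor_name)
  df$waves <- as.character(df$waves)
  for (col in c("n", CORR_COLS, "original_b", "pct_male", "mean_age")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (anyNA(df$effect_id) || anyDuplicated(df$effect_id)) {
    stop("validation error: effect_id must be present and unique", call. = FALSE)
  }
  if (anyNA(df$n) || any(df$n < 4) || any(df$n != round(df$n))) {
    stop("validation error: n must be an integer >= 4 for every record", call. = FALSE)
  }
  for (col in CORR_COLS) {
    bad <- which(!is.na(df[[col]]) & abs(df[[col]]) > 1)
    if (length(bad)) {
      stop(sprintf("validation error: %s = %g outside [-1, 1] for effect_id %s",
                   col, df[[col]][bad[1]], df$effect_id[bad[1]]), call. = FALSE)
    }
  }
  bad_pm <- which(!is.na(df$pct_male) & (df$pct_male < 0 | df$pct_male > 100))
  if (length(bad_pm)) {
    stop(sprintf("validation error: pct_male outside [0, 100] for effect_id %s",
                 df$effect_id[bad_pm[1]]), call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

# "-" and the unicode minus both occur in published tables; a bare dash is a
# missing-value marker, a leading one is a sign.
normalize_numeric_text <- function(x) {
  x <- gsub("−", "-", as.character(x))
  x <- gsub(",", "", trimws(x))
  x[x %in% c("", "-", "NA")] <- NA
  x
}

#' Read study records from CSV or JSON
#'
#' Expects one row/object per reanalyzed effect with the fields `effect_id`,
#' `n`, the six correlations `r_p1p2, r_p1e1, r_p1e2, r_p2e1, r_p2e2, r_e1e2`,
#' and optionally `predictor_name`, `waves`, `original_b`, `pct_male`,
#' `mean_age`. Unicode minus signs are normalized on read; a bare `-` is
#' treated as missing. All records are validated: unique `effect_id`,
#' integer `n >= 4`, correlations within [-1, 1]. Row order is preserved.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; guessed from the file extension by
#'   default.
#' @return A validated data frame of study records.
#' @export
load_studies <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- read.csv(path, colClasses = "character", check.names = TRUE,
                   fileEncoding = "UTF-8")
  } else {
    df <- jsonlite::fromJSON(path)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  }
  for (col in intersect(names(df), c("n", CORR_COLS, "original_b", "pct_male", "mean_age"))) {
    df[[col]] <- suppressWarnings(as.numeric(normalize_numeric_text(df[[col]])))
  }
  validate_studies(df)
}

#' Write study records to CSV or JSON
#'
#' Inverse of [load_studies()]; `load_studies(write_studies(x, path))`
#' round-trips any valid record set.
#'
#' @param records Validated study records.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension by default.
#' @export
write_studies <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  records <- validate_studies(records)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    write.csv(records, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", na = "null", digits = NA)
  }
  invisible(path)
}

#' The 23 reanalyzed effects: printed study characteristics
#'
#' Characteristics of the 13 two-wave panel studies (23 cross-lagged effects)
#' whose claimed prospective effects on burnout/exhaustion the scrutiny
#' pipeline targets: sample size, wave pair, predictor name, the original
#' study's standardized cross-lagged effect, and sample demographics. The six
#' pairwise correlations are NOT part of the printed record and are returned
#' as `NA`; they must be supplied by the user (e.g., from the studies' open
#' deposit) before [scrutinize_study()] can run.
#'
#' @return A data frame of 23 validated study records.
#' @export
builtin_table1 <- function() {
  df <- data.frame(
    effect_id = c("1.1", "2.1", "3.1", "3.2", "3.3", "4.1", "4.2", "4.3",
                  "5.1", "5.2", "6.1", "7.1", "7.2", "8.1", "8.2", "8.3",
                  "9.1", "10.1", "11.1", "11.2", "11.3", "12.1", "13.1"),
    n = c(651, 1314, 261, 261, 261, 2235, 2235, 2235, 1703, 1703, 1702, 664,
          664, 1226, 1226, 1226, 142, 191, 542, 542, 542, 155, 349),
    predictor_name = c("Organizational demands", "Job insecurity",
                       "Work family interference", "Avoidance", "Perfectionism",
                       "Work to family conflict", "Work to family facilitation",
                       "Family to work conflict", "Work role conflict",
                       "Work family conflict", "Psychological health complaints",
                       "Affective rumination", "Affective rumination",
                       "Sleep problems", "Sleep problems", "Sleep problems",
                       "Grades", "Perfectionistic concerns", "Depression",
                       "Depression", "Depression", "Incivility", "Work ability"),
    waves = c("1-2", "1-2", "1-2", "1-2", "1-2", "1-2", "1-2", "1-2", "1-2",
              "1-2", "1-2", "1-2", "2-3", "1-2", "2-3", "3-4", "1-2", "1-2",
              "1-2", "2-3", "3-4", "1-2", "1-2"),
    original_b = c(0.11, 0.05, 0.14, 0.10, 0.12, 0.34, -0.24, 0.06, 0.06,
                   0.06, 0.16, 0.14, 0.11, 0.24, 0.23, 0.33, -0.14, 0.22,
                   0.11, 0.12, 0.13, 0.18, -0.16),
    pct_male = c(90, 32, 52, 52, 52, 54, 54, 54, 78, 78, 78, 42, 42, 50, 50,
                 50, 24, 44, 46, 46, 46, NA, 0),
    mean_age = c(35, 43, 46, 46, 46, 45, 45, 45, NA, NA, NA, 48, 48, 13, 13,
                 13, 21, 43, 23, 23, 23, NA, 49),
    stringsAsFactors = FALSE
  )
  validate_studies(df)
}

#' Summarize a study collection
#'
#' Study-level descriptives: records sharing the same study index (the
#' `effect_id` prefix before the dot) are deduplicated to one row per study
#' before averaging, and missing demographics are excluded from their means.
#'
#' @param records Validated study records (at least one).
#' @return A `study_summary`: `n_studies`, `n_effects`, `n_min`, `n_max`,
#'   `n_mean`, `pct_male_mean`, `age_mean`.
#' @export
summarize_studies <- function(records) {
  records <- validate_studies(records)
  if (nrow(records) == 0) stop("at least one study record is required", call. = FALSE)
  study <- sub("\\..*$", "", records$effect_id)
  one <- records[!duplicated(study), ]
  structure(list(
    n_studies = nrow(one), n_effects = nrow(records),
    n_min = min(one$n), n_max = max(one$n), n_mean = mean(one$n),
    pct_male_mean = mean(one$pct_male, na.rm = TRUE),
    age_mean = mean(one$mean_age, na.rm = TRUE)
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("%d studies, %d effects; N in [%g, %g], M = %.1f; %% male M = %.1f; age M = %.1f\n",
              x$n_studies, x$n_effects, x$n_min, x$n_max, x$n_mean,
              x$pct_male_mean, x$age_mean))
  invisible(x)
}

#' Write scrutiny results as a formatted table
#'
#' One row per effect with the three focal effects (2-decimal estimate, 95%
#' interval, significance stars: * p<0.05, ** p<0.01, *** p<0.001), the
#' artifactualness-model chi-square, CFI and RMSEA with its 90% interval, and
#' the verdict label. Written as CSV; set `markdown` to also render a
#' Markdown table.
#'
#' @param results A list of `scrutiny_result` objects ([scrutinize_all()]).
#' @param path Output CSV path.
#' @param markdown Optional path for a Markdown rendering.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, markdown = NULL) {
  if (inherits(results, "scrutiny_result")) results <- list(results)
  results <- Filter(function(r) inherits(r, "scrutiny_result"), results)
  if (length(results) == 0) stop("results must contain at least one scrutiny result", call. = FALSE)
  df <- do.call(rbind, lapply(results, function(r) {
    row <- data.frame(effect_id = r$effect_id, stringsAsFactors = FALSE)
    for (m in c("A", "B", "C")) {
      e <- r[[paste0("effect_", m)]]
      row[[paste0("b_", m)]] <- fmt2(e$b)
      row[[paste0("ci_low_", m)]] <- fmt2(e$ci95[1])
      row[[paste0("ci_high_", m)]] <- fmt2(e$ci95[2])
      row[[paste0("stars_", m)]] <- p_stars(e$p_value)
    }
    row$chi2_D <- sprintf("%.1f", r$fit_D$chi2)
    row$cfi_D <- fmt2(r$fit_D$cfi)
    row$rmsea_D <- fmt2(r$fit_D$rmsea)
    row$rmsea_low_D <- fmt2(r$fit_D$rmsea_ci90[1])
    row$rmsea_high_D <- fmt2(r$fit_D$rmsea_ci90[2])
    row$verdict <- r$verdict
    row
  }))
  tryCatch(write.csv(df, path, row.names = FALSE),
           error = function(e) stop(sprintf("cannot write results to '%s': %s",
                                            path, conditionMessage(e)), call. = FALSE))
  if (!is.null(markdown)) {
    cell <- function(r, m) {
      e <- r[[paste0("effect_", m)]]
      format_effect_cell(e$b, e$ci95[1], e$ci95[2], e$p_value)
    }
    lines <- c(
      "| Effect | A | B | C | chi2 | CFI | RMSEA [90% CI] | Verdict |",
      "|---|---|---|---|---|---|---|---|",
      vapply(results, function(r) {
        sprintf("| %s | %s | %s | %s | %.1f | %.2f | %s [%s; %s] | %s |",
                r$effect_id, cell(r, "A"), cell(r, "B"), cell(r, "C"),
                r$fit_D$chi2, r$fit_D$cfi, fmt2(r$fit_D$rmsea),
                fmt2(r$fit_D$rmsea_ci90[1]), fmt2(r$fit_D$rmsea_ci90[2]),
                r$verdict)
      }, character(1))
    )
    writeLines(lines, markdown)
  }
  invisible(path)
}
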