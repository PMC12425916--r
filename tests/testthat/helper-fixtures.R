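# Shared fixtures, generated in code.

# Random positive-definite correlation matrix over (P1, P2, E1, E2):
# two-factor loadings plus a diagonal, normalized to unit diagonal.
random_corr4 <- function() {
  W <- matrix(rnorm(8, sd = 0.6), 4, 2)
  S <- tcrossprod(W) + diag(runif(4, 0.4, 1.2))
  correlation_matrix4(cov2cor(S))
}

make_record <- function(effect_id = "11.1", n = 542,
                        r_p1p2 = 0.60, r_p1e1 = 0.30, r_p1e2 = 0.40,
                        r_p2e1 = 0.25, r_p2e2 = 0.45, r_e1e2 = 0.55,
                        predictor_name = "Depression", waves = "1-2",
                        original_b = 0.11, pct_male = 46, mean_age = 23) {
  data.frame(effect_id = effect_id, n = n, r_p1p2 = r_p1p2, r_p1e1 = r_p1e1,
             r_p1e2 = r_p1e2, r_p2e1 = r_p2e1, r_p2e2 = r_p2e2,
             r_e1e2 = r_e1e2, predictor_name = predictor_name, waves = waves,
             original_b = original_b, pct_male = pct_male, mean_age = mean_age,
             stringsAsFactors = FALSE)
}

# Record whose correlations come from a known-truth DGP.
record_from_dgp <- function(dgp, n = 1000, effect_id = "synthetic") {
  R <- if (inherits(dgp, "genuine_dgp")) {
    implied_correlations_genuine(dgp)
  } else {
    implied_correlations_artifactual(dgp)
  }
  make_record(effect_id = effect_id, n = n,
              r_p1p2 = R["P1", "P2"], r_p1e1 = R["P1", "E1"],
              r_p1e2 = R["P1", "E2"], r_p2e1 = R["P2", "E1"],
              r_p2e2 = R["P2", "E2"], r_e1e2 = R["E1", "E2"])
}

# Minimal hand-built effect estimate for classifier tests.
fake_effect <- function(b, p, model = "clpm") {
  structure(list(model = model, b = b, se = abs(b) / 2 + 0.01,
                 ci95 = b + c(-1, 1) * 0.05, p_value = p,
                 significant = p < 0.05),
            class = "effect_estimate")
}

fake_fitidx <- function(cfi, chi2 = 1, df = 6, n = 500) {
  structure(list(chi2 = chi2, df = df, p_value = 0.5, cfi = cfi, tli = cfi,
                 rmsea = 0.01, rmsea_ci90 = c(0, 0.05), srmr = 0.01),
            class = "fit_indices")
}

cov_n <- function(x) clpmscrutiny:::cov_ml(x)
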