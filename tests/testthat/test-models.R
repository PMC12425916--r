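test_that("closed-form betas match their defining expressions and edge cases", {
  # lagged: numerator vanishing, zero-order reduction, derived value
  expect_equal(beta_lagged(0.18, 0.3, 0.6), 0)
  expect_equal(beta_lagged(0.4, 0, 0.5), 0.4)
  expect_equal(beta_lagged(0.5, 0.3, 0.6), 0.32 / 0.91, tolerance = 1e-12)
  expect_error(beta_lagged(0.2, 1, 0.5), "collinearity")

  # change score: null at equality, antisymmetry, derived value
  expect_equal(beta_change(0.3, 0.3, 0.7), 0)
  expect_equal(beta_change(0.5, 0.3, 0.6), 0.2 / sqrt(0.8), tolerance = 1e-12)
  expect_equal(beta_change(0.3, 0.5, 0.6), -beta_change(0.5, 0.3, 0.6))
  expect_error(beta_change(0.2, 0.1, 1), "zero-variance")

  # reversed: numerator vanishing, derived value, zero-order reduction
  expect_equal(beta_reversed(0.3, 0.5, 0.6), 0)
  expect_equal(beta_reversed(0.4, 0.2, 0.5), 0.3125, tolerance = 1e-12)
  expect_equal(beta_reversed(0.4, 0, 0.5), 0.4)
  expect_error(beta_reversed(0.2, -1, 0.5), "collinearity")

  # lagged and reversed coincide under exchange of the outcome waves
  set.seed(42)
  for (i in 1:20) {
    r <- runif(3, -0.6, 0.6)
    expect_equal(beta_reversed(r[1], r[2], r[3]), beta_lagged(r[1], r[2], r[3]),
                 tolerance = 1e-12)
  }
})

test_that("closed forms agree with OLS on exact-mode data (independent route)", {
  R <- correlation_matrix(make_record())
  d <- as.data.frame(sample_mvn(R, 400, "exact", seed = 9)$scores)
  n <- nrow(d)
  std <- function(x) x / sd(x)   # columns already have mean 0, sd 1

  ols_a <- coef(lm(E2 ~ P1 + E1, data = d))[["P1"]]
  expect_equal(ols_a, beta_lagged(R["P1", "E2"], R["P1", "E1"], R["E1", "E2"]),
               tolerance = 1e-10)

  ols_b <- coef(lm(E1 ~ P1 + E2, data = d))[["P1"]]
  expect_equal(ols_b, beta_reversed(R["P1", "E1"], R["P1", "E2"], R["E1", "E2"]),
               tolerance = 1e-10)

  diff_std <- (d$E2 - d$E1) / sd(d$E2 - d$E1)
  ols_c <- coef(lm(diff_std ~ d$P1))[[2]]
  expect_equal(ols_c, beta_change(R["P1", "E2"], R["P1", "E1"], R["E1", "E2"]),
               tolerance = 1e-10)
})

test_that("the four builders have the documented shape", {
  a <- build_clpm()
  expect_length(a$labels, 10)
  expect_equal(length(a$observed) * (length(a$observed) + 1) / 2 - length(a$labels), 0)
  expect_equal(a$focal, "b_pe")

  b <- build_reversed_clpm()
  expect_length(b$labels, 6)
  expect_identical(b$observed, c("P1", "E1", "E2"))

  c3 <- build_lcsm()
  expect_length(c3$labels, 10)
  expect_identical(c3$focal_to, "dE")
  expect_identical(sort(setdiff(c3$variables, c3$observed)), c("dE", "dP"))

  d4 <- build_artifact_model(1)
  expect_length(d4$labels, 4)
  expect_equal(length(d4$observed) * (length(d4$observed) + 1) / 2 - length(d4$labels), 6)
  expect_error(build_artifact_model(0), "sign")
})

test_that("fitted focal effects equal the closed forms on exact-mode data", {
  set.seed(77)
  n <- 200
  for (i in 1:25) {
    R <- random_corr4()
    d <- sample_mvn(R, n, "exact", seed = i)
    s <- cov_n(d$scores)

    fa <- focal_effect(fit_ml(build_clpm(), s, n), "clpm")
    expect_equal(fa$b, beta_lagged(R["P1", "E2"], R["P1", "E1"], R["E1", "E2"]),
                 tolerance = 1e-6)

    fb <- focal_effect(fit_ml(build_reversed_clpm(), s, n), "reversed")
    expect_equal(fb$b, beta_reversed(R["P1", "E1"], R["P1", "E2"], R["E1", "E2"]),
                 tolerance = 1e-6)

    fc <- focal_effect(fit_ml(build_lcsm(), s, n), "lcsm")
    expect_equal(fc$b, beta_change(R["P1", "E2"], R["P1", "E1"], R["E1", "E2"]),
                 tolerance = 1e-6)
  }
})

test_that("the artifact model fits its own data perfectly and recovers parameters", {
  theta_true <- c(v_gneg = 0.3, theta_p = 0.7, theta_e = 0.7, state_cov = 0.1)
  R <- implied_correlations_artifactual(artifactual_dgp(0.3, 1, 0.7, 0.7, 0.1))
  d <- sample_mvn(R, 1000, "exact", seed = 31)
  s <- cov_n(d$scores)
  spec <- build_artifact_model(1)
  fit <- fit_ml(spec, s, 1000, start = spec$start_fn(s))
  expect_lt(fit$chi2, 1e-6)
  # the engine fits the denominator-n covariance (target * (n-1)/n); parameter
  # recovery is judged on the back-scaled estimates
  scale <- 1000 / 999
  expect_lt(max(abs(fit$theta[names(theta_true)] * scale - theta_true)), 1e-4)
  fi <- fit_indices(fit)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$rmsea, 0)
})

test_that("the artifact model's implied cross-block is rank one away from state terms", {
  for (sgn in c(1, -1)) {
    theta <- c(v_gneg = 0.25, theta_p = 0.8, theta_e = 0.6, state_cov = 0.08)
    sig <- model_implied_sigma(build_artifact_model(sgn), theta)
    cross <- sig[c("P1", "P2"), c("E1", "E2")]
    cross["P1", "E1"] <- cross["P1", "E1"] - theta[["state_cov"]]
    cross["P2", "E2"] <- cross["P2", "E2"] - theta[["state_cov"]]
    expect_lt(abs(det(cross)), 1e-12)             # rank 1
    expect_true(all(abs(cross - sgn * 0.25) < 1e-12))
    if (sgn < 0) expect_true(all(cross < 0))
  }
})

test_that("sign logic holds across the genuine-effect parameter grid", {
  for (stab in c(0.2, 0.45, 0.7)) {
    for (cross in c(0.1, 0.25, 0.4)) {
      dgp <- genuine_dgp(stability_p = stab, stability_e = stab,
                         cross_pe = cross, cross_ep = 0.1, r0 = 0)
      R <- implied_correlations_genuine(dgp)
      a <- beta_lagged(R["P1", "E2"], R["P1", "E1"], R["E1", "E2"])
      b <- beta_reversed(R["P1", "E1"], R["P1", "E2"], R["E1", "E2"])
      cc <- beta_change(R["P1", "E2"], R["P1", "E1"], R["E1", "E2"])
      expect_gt(a, 0)
      expect_lt(b, 0)
      expect_gt(cc, 0)
    }
  }
  # fitted spot-check of the same signature
  dgp <- genuine_dgp(stability_p = 0.45, stability_e = 0.45, cross_pe = 0.25, r0 = 0)
  d <- sample_mvn(implied_correlations_genuine(dgp), 300, "exact", seed = 4)
  s <- cov_n(d$scores)
  expect_gt(focal_effect(fit_ml(build_clpm(), s, 300), "clpm")$b, 0)
  expect_lt(focal_effect(fit_ml(build_reversed_clpm(), s, 300), "reversed")$b, 0)
  expect_gt(focal_effect(fit_ml(build_lcsm(), s, 300), "lcsm")$b, 0)
})

test_that("focal extraction enforces convergence and Wald consistency", {
  R <- correlation_matrix4(diag(4))
  d <- sample_mvn(R, 200, "exact", seed = 6)
  fit <- fit_ml(build_clpm(), cov_n(d$scores), 200)
  eff <- focal_effect(fit, "clpm")
  expect_equal(eff$b, 0, tolerance = 1e-8)
  expect_equal(eff$p_value, 1, tolerance = 1e-6)
  expect_false(eff$significant)
  expect_true(eff$ci95[1] <= eff$b && eff$b <= eff$ci95[2])

  broken <- fit
  broken$converged <- FALSE
  expect_error(focal_effect(broken, "clpm"), "non-converged")
})
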