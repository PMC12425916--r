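# Tiny hand-built specs used throughout.
spec_two_var <- function(b = 0.6) {
  vars <- c("x", "y")
  Af <- matrix(0, 2, 2); Al <- matrix(NA_character_, 2, 2)
  Sf <- matrix(0, 2, 2); Sl <- matrix(NA_character_, 2, 2)
  Af[2, 1] <- b                      # y <- x fixed at b
  Sf[1, 1] <- 1; Sf[2, 2] <- 1 - b^2
  sem_spec(vars, vars, Af, Al, Sf, Sl, name = "path")
}

test_that("the RAM-implied covariance follows the path-tracing rules", {
  # no paths, unit variances: identity
  v <- c("a", "b", "c")
  Sf <- diag(3)
  spec0 <- sem_spec(v, v, matrix(0, 3, 3), matrix(NA_character_, 3, 3),
                    Sf, matrix(NA_character_, 3, 3))
  expect_equal(model_implied_sigma(spec0, numeric(0)), diag(3), ignore_attr = TRUE)

  # single standardized path x -> y: implied correlation equals the coefficient
  for (b in c(-0.8, 0.3, 0.6)) {
    sig <- model_implied_sigma(spec_two_var(b), numeric(0))
    expect_equal(sig["y", "x"], b, tolerance = 1e-12)
    expect_equal(diag(sig), c(x = 1, y = 1), tolerance = 1e-12)
  }

  # artifactualness model vs. brute-force factor algebra at a chosen point
  theta <- c(v_gneg = 0.28, theta_p = 0.6, theta_e = 0.75, state_cov = 0.07)
  sgn <- -1
  sig <- model_implied_sigma(build_artifact_model(sgn), theta)
  L <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))        # indicators on gP, gE
  g <- c(1, sgn)                                        # gP, gE on gNeg
  Phi <- theta[["v_gneg"]] * (g %*% t(g))               # factor covariance
  resid <- diag(c(theta[["theta_p"]], theta[["theta_p"]],
                  theta[["theta_e"]], theta[["theta_e"]]))
  resid[1, 3] <- resid[3, 1] <- theta[["state_cov"]]
  resid[2, 4] <- resid[4, 2] <- theta[["state_cov"]]
  hand <- L %*% Phi %*% t(L) + resid
  expect_equal(unclass(sig), hand, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("the ML discrepancy is zero at equality and positive elsewhere", {
  set.seed(3)
  S <- cov_n(matrix(rnorm(200), 50, 4))
  expect_equal(ml_discrepancy(S, S), 0, tolerance = 1e-12)
  expect_equal(ml_discrepancy(2 * diag(2), diag(2)), 2 * log(2) - 1, tolerance = 1e-12)
  for (i in 1:10) {
    P <- S + tcrossprod(rnorm(4, sd = 0.2))
    expect_gt(ml_discrepancy(P, S), 0)
  }
  expect_error(ml_discrepancy(diag(2) * -1, diag(2)), "positive definite")
})

test_that("saturated fits reproduce the sample moments with zero chi-square", {
  set.seed(11)
  for (i in 1:5) {
    R <- random_corr4()
    d <- sample_mvn(R, 150, "exact", seed = i)
    s <- cov_n(d$scores)
    fit <- fit_ml(build_clpm(), s, 150)
    expect_equal(fit$df, 0L)
    expect_lt(fit$chi2, 1e-8)
    expect_lt(max(abs(fit$sigma_hat - s)), 1e-8)
    expect_true(fit$converged)
  }
})

test_that("chi-square respects likelihood monotonicity for nested models", {
  # the artifact model with state covariance fixed to zero is nested in the
  # free-state version; its chi-square can never be smaller
  d <- sample_mvn(implied_correlations_genuine(genuine_dgp(r0 = 0.2)),
                  500, "exact", seed = 5)
  s <- cov_n(d$scores)
  full <- build_artifact_model(1)
  restricted <- full
  restricted$S_label[restricted$S_label == "state_cov"] <- NA
  restricted <- sem_spec(full$variables, full$observed, full$A_fixed,
                         full$A_label, full$S_fixed, restricted$S_label,
                         name = "artifact-nostate")
  f_full <- fit_ml(full, s, 500, start = full$start_fn(s))
  f_res <- fit_ml(restricted, s, 500)
  expect_equal(f_res$df, f_full$df + 1)
  expect_gte(f_res$chi2, f_full$chi2 - 1e-8)
})

test_that("standard errors scale as one over the square root of n", {
  R <- correlation_matrix(make_record())
  fits <- lapply(c(500, 2000), function(n) {
    d <- sample_mvn(R, n, "exact", seed = 3)
    fit_ml(build_clpm(), cov_n(d$scores), n)
  })
  ratio <- fits[[1]]$se / fits[[2]]$se
  expect_equal(unname(ratio), rep(2, length(ratio)), tolerance = 0.02)
})

test_that("under-identified models raise an identification error", {
  # free path x -> y plus free covariance(x, y): 4 parameters, 3 moments
  vars <- c("x", "y")
  Al <- matrix(NA_character_, 2, 2); Al[2, 1] <- "b"
  Sl <- matrix(c("vx", "cxy", "cxy", "vy"), 2, 2)
  spec <- sem_spec(vars, vars, matrix(0, 2, 2), Al, matrix(0, 2, 2), Sl,
                   name = "underid")
  s <- matrix(c(1, 0.4, 0.4, 1), 2, 2, dimnames = list(vars, vars))
  expect_error(suppressWarnings(fit_ml(spec, s, 100)), "identified")
})

test_that("the independence baseline matches its analytic solution and a full fit", {
  expect_equal(baseline_chi2(diag(4), 200)$chi2, 0)
  expect_equal(baseline_chi2(diag(4), 200)$df, 6L)
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(baseline_chi2(S2, 100)$chi2, -100 * log(1 - 0.25), tolerance = 1e-10)

  # dual route: explicit independence spec fitted with the engine
  set.seed(21)
  R <- random_corr4()
  vars <- rownames(R)
  Sl <- matrix(NA_character_, 4, 4); diag(Sl) <- paste0("v", 1:4)
  ind <- sem_spec(vars, vars, matrix(0, 4, 4), matrix(NA_character_, 4, 4),
                  matrix(0, 4, 4), Sl, name = "independence")
  fit <- fit_ml(ind, unclass(R), 300)
  expect_equal(fit$chi2, baseline_chi2(unclass(R), 300)$chi2, tolerance = 1e-6)
  expect_equal(fit$df, baseline_chi2(unclass(R), 300)$df)
})

test_that("fit indices follow their defining formulas and truncation rules", {
  # perfect fit at df = 6
  d <- sample_mvn(implied_correlations_artifactual(artifactual_dgp()),
                  800, "exact", seed = 2)
  s <- cov_n(d$scores)
  spec <- build_artifact_model(1)
  fit <- fit_ml(spec, s, 800, start = spec$start_fn(s))
  fi <- fit_indices(fit)
  expect_equal(fi$cfi, 1)
  expect_equal(fi$tli, 1)
  expect_equal(fi$rmsea, 0)
  expect_lt(fi$srmr, 1e-6)
  expect_equal(fi$rmsea_ci90[1], 0)

  # saturated model: RMSEA/TLI not applicable
  sat <- fit_ml(build_clpm(), s, 800)
  fs <- fit_indices(sat)
  expect_true(is.na(fs$rmsea) && is.na(fs$tli))
  expect_equal(fs$cfi, 1)
})

test_that("RMSEA point values reproduce the printed fit-index arithmetic", {
  expect_equal(round(rmsea(50.6, 6, 1226), 2), 0.08)
  expect_equal(round(rmsea(21.0, 6, 542), 2), 0.07)
  expect_equal(rmsea(3, 6, 500), 0)  # chi2 below df floors at zero
})

test_that("the RMSEA interval inverts the noncentral chi-square correctly", {
  expect_equal(rmsea_ci(3, 6, 500)[1], 0)
  expect_equal(round(rmsea_ci(50.6, 6, 1226), 2), c(0.06, 0.10))
  expect_equal(round(rmsea_ci(21.0, 6, 542), 2), c(0.04, 0.10))
  # both bounds are monotone in chi2
  grid <- t(vapply(c(8, 15, 30, 60), function(x2) rmsea_ci(x2, 6, 400), numeric(2)))
  expect_true(all(diff(grid[, 1]) >= 0))
  expect_true(all(diff(grid[, 2]) >= 0))
  # the point estimate always lies inside the interval
  for (x2 in c(2, 10, 40)) {
    ci <- rmsea_ci(x2, 6, 300)
    r <- rmsea(x2, 6, 300)
    expect_true(ci[1] <= r && r <= ci[2])
  }
})

test_that("model specifications survive a JSON round-trip", {
  for (spec in list(build_clpm(), build_reversed_clpm(), build_lcsm(),
                    build_artifact_model(-1))) {
    back <- spec_from_json(spec_to_json(spec))
    expect_equal(back$A_fixed, spec$A_fixed)
    expect_equal(back$S_fixed, spec$S_fixed)
    expect_equal(back$A_label, spec$A_label)
    expect_equal(back$S_label, spec$S_label)
    expect_equal(back$labels, spec$labels)
    expect_equal(back$focal, spec$focal)
  }
  # equation rendering names every free parameter
  eq <- sem_equations(build_clpm())
  expect_true(any(grepl("E2 ~ .*free\\(b_pe\\)\\*P1", eq)))
  expect_true(any(grepl("~~", eq)))
})
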