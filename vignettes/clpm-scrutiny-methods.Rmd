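---
title: "Scrutinizing cross-lagged panel effects: models, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scrutinizing cross-lagged panel effects: models, assumptions, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clpmscrutiny)
```

## The problem

Two-wave panel studies routinely report a "prospective effect": a predictor
measured at wave 1 (say, depression, sleep problems, or job insecurity)
predicts an outcome such as burnout or exhaustion at wave 2 *after adjusting
for the wave-1 outcome*, and the adjusted coefficient is read causally. That
reading is fragile. When measurements carry occasion-specific error and the
predictor correlates with the outcome's wave-1 residual, regression toward
the mean alone produces a nonzero adjusted cross-lagged coefficient — with no
direct effect of the predictor on the outcome at all.

`clpmscrutiny` operationalizes a scrutiny protocol for such claims. Given a
study's sample size and the six pairwise correlations among the predictor and
the outcome at two occasions (P1, P2, E1, E2), it simulates standardized data
reproducing those correlations, fits four complementary structural models,
and asks whether their focal effects converge on the genuine-effect signature
or on the artifactual one. Because standardized regression effects are
functions of the correlation matrix, a simulated dataset with the same
correlations and sample size yields the same standardized estimates and the
same significance decisions as the original data would — the original raw
data are not needed.

## The four models

All variables are standardized; every model is fitted to the sample
covariance matrix by normal-theory maximum likelihood.

**A — Cross-lagged panel model (CLPM).** E2 and P2 are each regressed on both
wave-1 variables; wave-1 variables covary, wave-2 residuals covary. The model
is saturated (df = 0). The focal path P1 → E2 has the closed form

$$\beta_A = \frac{r_{P_1E_2} - r_{P_1E_1}\,r_{E_1E_2}}{1 - r_{P_1E_1}^2}.$$

**B — Time-reversed CLPM.** E1 is regressed on E2 and P1 (three observed
variables; the second wave of the predictor plays no role in this
regression). If the predictor genuinely *raises* the outcome over time, then
among people who end at the same E2, those with high P1 must have started
lower — the reversed focal path P1 → E1 should have the *opposite* sign of
$\beta_A$:

$$\beta_B = \frac{r_{P_1E_1} - r_{P_1E_2}\,r_{E_1E_2}}{1 - r_{P_1E_2}^2}.$$

**C — Latent change score model (LCSM).** Change is isolated as a latent
variable via fixed unit loadings, $E_2 = E_1 + \Delta E$ (zero wave-2
residual), and $\Delta E$ is regressed on P1 (and $\Delta P$ on E1). A genuine
increasing effect must show up as a positive effect on *change*. In the
parameterization used here — the change disturbance covaries freely with the
same construct's wave-1 score instead of a proportional-change regression —
the standardized focal effect equals the difference-score coefficient
exactly:

$$\beta_C = \frac{r_{P_1E_2} - r_{P_1E_1}}{\sqrt{2(1 - r_{E_1E_2})}}.$$

A proportional-change variant would absorb part of the wave-1 association
into a $\Delta E \leftarrow E_1$ path; the covariance parameterization was
chosen precisely because it reproduces the difference-score effect, which is
the quantity the scrutiny logic interprets. These three closed forms also
serve as independent oracles for the fitted models in the test suite.

**D — Artifactualness model.** A structural model with *no* direct
predictor–outcome paths: P1, P2 load (fixed 1) on a general predictor factor,
E1, E2 on a general outcome factor, and both factors load on a second-order
"general negativity" factor — the outcome loading fixed to +1 or −1 according
to the sign of the predictor–outcome correlations. Same-occasion scores share
one state covariance (transient influences such as momentary mood). The free
parameters are four: the second-order factor variance, one residual variance
shared by the predictor indicators, one shared by the outcome indicators, and
the state covariance — hence df = 6. If this no-direct-effect model fits the
correlations well, the observed cross-lagged coefficient is explainable
without any prospective effect.

## The verdict rule

The scrutiny logic is qualitative — sign convergence across models — and the
package operationalizes it with explicit, configurable thresholds
(`verdict_config()`, defaults α = 0.05 and CFI ≥ 0.95):

* `consistent_with_genuine`: A significant, B opposite-signed, C significant
  and same-signed as A.
* `artifactual_pattern`: A significant, B *same*-signed, C non-significant or
  opposite-signed, and model D fits well.
* `inconclusive`: everything else — deliberately including hedged cases where
  B is non-significant and C shares A's sign without reaching significance.

The sign of model D's second-order loading is taken from the wave-1
cross-correlation; when the two waves disagree in sign a warning is raised
and wave 1 wins, and correlations below 1e-8 in magnitude are treated as
signless. The verdict vocabulary says *pattern*, not *proof*: a well-fitting
artifactualness model shows the data *could* have arisen without direct
effects, never that they did, and several different models can fit the same
correlations equally well.

## Simulation design

`sample_mvn()` draws from a zero-mean multivariate normal with the target
correlation matrix as covariance, in two modes:

* **exact** (default): draws are re-centered, whitened by the sample factor
  and re-colored by the target factor, so the sample correlation matrix
  equals the target to machine precision and every column has mean 0, SD 1.
  Standardized estimates are then *deterministic* functions of the target —
  re-running with another seed changes nothing beyond 1e-8 — which makes
  study-level scrutiny reproducible and makes the closed-form oracle
  comparisons sharp.
* **stochastic**: plain i.i.d. draws, used by the Monte-Carlo recovery
  experiments where sampling variability is the object of study.

No missing values are generated. One technical note: the engine fits the
denominator-*n* covariance matrix, while exact-mode standardization matches
the denominator-(n−1) correlation. The factor (n−1)/n cancels in every
standardized quantity and, because all four models are scale-equivariant, in
the chi-square as well; raw variance estimates are smaller by that factor.

## The estimation engine

The engine is a compact RAM-parameterized ML fitter (`sem_spec()`,
`fit_ml()`): implied covariance $F(I-A)^{-1}S(I-A)^{-\top}F^\top$, discrepancy
$\log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$, quasi-Newton (BFGS)
minimization with analytic gradients followed by Fisher-scoring polish steps.
Numerical choices that matter:

* **Convergence** is declared when the largest absolute unscaled parameter
  change between iterations falls below 0.0001 or the gradient norm below
  1e-8; the polish loop typically drives the gradient to ~1e-12, which is why
  saturated fits agree with the closed forms to better than 1e-6.
  Non-convergence is flagged on the fit and `focal_effect()` refuses to read
  from a non-converged fit.
* **Variance parameters** are log-transformed during iteration so the implied
  matrix stays positive definite; estimates and standard errors are reported
  on the natural scale.
* **Start values** default to 0.1 for paths and covariances and half the mean
  observed variance for variances; the four builders also attach closed-form
  moment-based starts (`spec$start_fn`) which the pipeline uses for speed.
  The oracle tests deliberately run from the *default* starts so that the
  optimizer, not the initialization, is what is being validated.
* **Standard errors** come from the inverse expected information at the
  optimum; focal effects are standardized through the fitted model's own
  implied variances and their uncertainty propagated by the delta method.
  All 95% intervals are Wald intervals (±1.96 SE), so `significant` is
  equivalent to the interval excluding zero.
* **Chi-square multiplier** is *n* (the `"n-1"` convention is available; at
  the sample sizes involved the two are indistinguishable at printed
  precision).
* **Identification** is checked empirically: a rank-deficient expected
  information matrix at the optimum raises an error rather than returning
  unstable estimates.

Fit indices follow the standard definitions: CFI and TLI against the
independence baseline (whose ML solution is analytic,
$\chi^2_b = -n\log|R|$), both truncated at 1; RMSEA
$\sqrt{\max(\chi^2-df,0)/(df\,n)}$ with its 90% interval obtained by
inverting the noncentral chi-square distribution; SRMR as the RMS
standardized residual over the unique elements including the diagonal (a
documented, configurable convention — dialects differ). For saturated models
RMSEA and TLI are reported as `NA`. The validation suite anchors this
arithmetic on two published artifact-model fit lines: χ² = 50.6 with
N = 1226 gives RMSEA 0.08 [0.06; 0.10], and χ² = 21.0 with N = 542 gives
0.07 [0.04; 0.10], both consistent with the four-parameter (df = 6) model
above.

## Known-truth generators

Two data-generating processes close the loop, making every pipeline stage
testable without any external data.

**Genuine process** (`genuine_dgp()`): standardized exogenous (P1, E1) with
correlation `r0`, then
$E_2 = s_e E_1 + c_{pe} P_1 + u$, $P_2 = s_p P_1 + c_{ep} E_1 + u'$, residual
variances solved in closed form for unit variances. Applying the CLPM closed
form to its implied correlations returns `cross_pe` *exactly* — an identity
the tests verify across the parameter grid. Defaults: stabilities 0.5
(typical one-year stability for affect-adjacent constructs), `cross_pe = 0.2`
(a clearly nonzero but realistic standardized effect), `cross_ep = 0.1`, and
`r0 = 0`.

The choice `r0 = 0` deserves its own paragraph. The time-reversal sign flip
is *not* an unconditional property of genuine effects: on the implied
correlations, $\beta_B < 0$ iff $r_0 < r_{P_1E_2}\, r_{E_1E_2}$, so a
baseline association large relative to the cross effect (e.g. stability 0.5,
cross 0.2, $r_0 = 0.3$) yields a genuine process whose reversed effect is
*same*-signed. With `r0 = 0` — no predictor–outcome association at baseline,
the canonical genuine-prospective-effect scenario — the flip holds for every
positive stability and cross effect, and the sign-logic tests run on that
grid. This is also an honest limitation of the protocol itself: a same-signed
reversed effect does not by itself refute genuineness, which is one reason
the hedged cases fall to `inconclusive`.

**Artifactual process** (`artifactual_dgp()`): the generating side of model
D. Defaults `var_gneg = 0.3` (the shared-disposition share of variance),
indicator residuals `1 - var_gneg` so variances are exactly 1, and
`state_cov = 0.1` for same-occasion transients. Its implied correlations have
zero direct cross-lagged effect by construction, yet the CLPM closed form
evaluates to about +0.21 — the regression-to-the-mean artifact, available in
closed form rather than by simulation.

`recovery_experiment()` wraps both: stochastic replicates → full scrutiny →
bias/RMSE of the CLPM focal effect, 95% CI coverage of the truth, spurious
significance rate, verdict rates, and mean model-D fit.

## Validation problem sizes

The shipped validation suite uses: 1000 random positive-definite correlation
matrices (exact mode, n = 200) for the oracle-equivalence sweep, agreement
required to 1e-6; 500 stochastic replicates at n = 1000 for each recovery
experiment (genuine: mean focal within 0.02 of truth, coverage in [93%, 97%],
genuine-verdict rate ≥ 90%; artifactual: spurious significance in a majority
of replicates, artifactual-verdict rate ≥ 90%, mean CFI ≥ 0.95); and exact
self-fit of model D at n = 1000 (chi-square < 1e-6, parameters recovered to
1e-4 after the (n−1)/n rescaling). These sizes give Monte-Carlo standard
errors around one percentage point on rate estimates while keeping the whole
suite inside a couple of minutes on one core.

## What passing does and does not show

The generators are linear-Gaussian, two-wave, complete-data processes. Real
panel data depart from all three: skewed and bounded scales, attrition,
more waves, covariate adjustment in the original analyses. Passing the
recovery experiments shows the *pipeline* — simulation, estimation,
standardization, classification — behaves correctly under its own
assumptions; it does not show that any particular empirical effect is
artifactual. Conversely, the per-study verdicts inherit every caveat above:
they compare the relative plausibility of sign patterns, and
`artifactual_pattern` should be read as "the claimed effect does not
withstand this scrutiny", never as proof that no effect exists. Multi-wave
studies are handled as successive wave pairs; covariate-adjusted originals
are compared against the simpler bivariate models fitted here, which is a
known and intended discrepancy source.
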