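---
title: "Methods: small-area variation in psychotropic dispensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area variation in psychotropic dispensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyvar)
```

`psyvar` implements a complete small-area variation analysis of
psychotropic dispensing to children and youth: standardized rates per
census division, classical variation statistics, per-division significance
tests, marginal regression models of dispensing correlates, and a
synthetic population generator that makes the whole chain testable without
restricted administrative data. This vignette is the package's account of
the underlying science: the models, the parameters that matter, the
numerical decisions, and what a passing test suite does and does not
establish.

## 1. The data model

One row per *person*: census division, age (0–24, banded 0–4 / 5–9 /
10–14 / 15–19 / 20–24), sex, neighbourhood income quintile (1 = lowest),
rural/urban residence, an ADG comorbidity cluster count (0–32, banded
0–5 / 6–9 / 10+), one dispensing indicator and one prescription count per
drug class (antidepressant, stimulant, antipsychotic, benzodiazepine), and
a sampling weight. The study design keeps *every* recipient of any class
(weight 1) and a 10% sample of non-recipients (weight 10), so weighted
sums recover population quantities.

One row per *division*: population per age-band × sex stratum, plus nine
area-level covariates — density of child/adolescent psychiatrists and
developmental pediatricians (per 100,000), density of child/youth mental
health agencies (per 1,000), the mental-health hospitalization/ED visit
rate (per 1,000), and six census measures (% post-secondary, % visible
minority, % non-citizen, % employed, % speaking neither official
language, mean household size).

## 2. Rates and standardization

Crude rates are weighted events over weighted population, per 1,000.
*Direct* standardization re-weights each division's stratum-specific rates
by the provincial stratum shares:

$$r_i^{std} = 1000 \sum_s \text{share}_s \frac{O_{is}}{w_{is}}.$$

The paper-style reports do not say whether direct or indirect
standardization produced the published rates; we chose direct because
directly standardized rates are comparable across areas, and we compute
the *indirect* expected counts

$$E_i = \sum_s \hat\rho_s\, w_{is}$$

(provincial stratum rates $\hat\rho_s$ applied to the division's strata)
anyway, because the SCV and the chi-square tests are defined on $O/E$.
When the reference is the pooled input itself, $\sum_i E_i = \sum_i O_i$
exactly; this conservation is tested to 1e-6 relative.

Empty strata contribute nothing to the direct sum and their reference
shares are renormalized away (with a logged message). Two numerator modes
are supported — persons dispensed (default, matching how such rates are
mapped) and prescriptions dispensed (matching the methods wording of the
source literature); all internal values are full precision, with rounding
only in formatted output.

## 3. Variation statistics

For $k$ areas with standardized rates $r_i$, populations $w_i$, observed
$O_i$ and expected $E_i$:

- **EQ** $= \max r_i / \min r_i$ (error if the minimum is 0 — the caller
  is pointed at the numerator mode or class with empty areas);
- **weighted CV** $= 100\sqrt{\sum w_i (r_i - \bar r_w)^2 / \sum w_i}/\bar r_w$;
- **SCV**, McPherson small-area form:
  $$\mathrm{SCV} = \frac{100}{k}\sum_i\left[\left(\frac{O_i-E_i}{E_i}\right)^2 - \frac{1}{E_i}\right].$$

The $1/E_i$ term subtracts the Poisson sampling variance, so the SCV
estimates the *systematic* (non-random) relative variation. Under a pure
Poisson null its expectation is 0 (tested over 2,000 simulated provinces);
under multiplicative log-normal mixing with log-variance $v$ it converges
to $100(e^v-1)$ (tested at $v \in \{0.05, 0.1\}$ against a replicate-
province Monte-Carlo oracle). Interpretation bands follow the published
convention, with the 5.4/5.5 gap in the prose resolved as half-open
intervals: $<3$ low, $[3, 5.5)$ moderate, $[5.5, 10]$ high, $>10$ very
high.

Each division is compared to the province by a one-sample proportion
chi-square with 1 df, treating the provincial rate as fixed:
$X^2 = (O-E)^2/E + ((N-O)-(N-E))^2/(N-E)$. The per-comparison alpha is
the familywise level divided by $k$ and rounded to one significant figure
(0.05/49 → 0.001); both raw and rounded values are recorded by the
pipeline.

Two subtleties worth knowing:

- Because $E_i$ is estimated from the pooled data, $\sum_i (O_i - E_i) = 0$;
  this absorbs roughly one degree of freedom and shrinks the SCV slightly
  relative to a fixed-expectation oracle. The test oracle therefore
  re-estimates $E$ per replicate.
- EQ and CV are invariant to rescaling all rates; the SCV's systematic
  term is scale-free in $O/E$ but its $1/E$ correction shrinks as counts
  grow, which the tests assert explicitly.

## 4. The regression model

The marginal model for dispensing counts is a log-link GEE. Persons are
aggregated into covariate-pattern cells within division; the cell outcome
is the recipient count and the cell offset is the log of summed weights,
which inflates the 10% non-recipient sample back to population scale. For
a log-link count model this aggregation is exact: collapsed and
uncollapsed data give identical estimating equations (tested).

Fisher scoring solves $\sum_c D_c' V_c^{-1}(y_c-\mu_c)=0$ with
$\mu = \exp(X\beta + \text{offset})$, variance function $\mu$
(quasi-Poisson; Pearson dispersion $\hat\phi$) or $\mu + \mu^2/\theta$
(negative binomial; $\theta$ by method of moments each iteration — the
original analyses were negative binomial but publish no $\theta$, so both
families are exposed and quasi-Poisson is the default), and working
correlation either independence or exchangeable ($\alpha$ by the standard
moment estimator over within-cluster residual cross-products; singleton
clusters contribute only to $\phi$). Convergence is
$\max|\Delta\beta| < 10^{-8}$ within 100 iterations, with score-norm
step-halving guarding each Gauss–Newton step. Reported covariance is
always the cluster-robust sandwich $B^{-1} M B^{-1}$; CIs use the
multiplier 1.959964 and are rounded to two decimals only in the formatted
table, where reference levels (age 5–9, female, urban, income quintile 1,
ADG 0–5) print as 1.00.

The solver was cross-checked two ways: with independence working
correlation it reproduces quasi-Poisson GLM point estimates to 1e-6 (and
its sandwich equals the HC0-robust GLM covariance when every cell is its
own cluster), and on a small exchangeable Poisson fixture it agrees with
an independent GEE implementation (statsmodels 0.14) to ~1e-8 on
coefficients, $\alpha$, and robust SEs; those verified numbers are frozen
in the test suite.

### When the exchangeable equation has no solution

A genuine methodological finding from this implementation: with
covariate-pattern cells of widely varying size inside large clusters, and
strong division-level heterogeneity (the default synthetic world), the
moment estimate of $\alpha$ reaches 0.4–0.6 and the cell-level
exchangeable estimating equation **has no root**. This was verified
independently — a reference GEE implementation diverges to overflow on the
identical design, and direct minimisation of the squared score bottoms out
far from zero — and is a known pathology of non-diagonal working
correlations (the implied correlation of Pearson residuals between cells
in fact depends strongly on cell size, so a single $\alpha$ badly
misweights the data). The solver does not hide this: it reports
`converged = FALSE` with the last iterate and the exit update size, the
formatted-table layer refuses unconverged fits, and the pipeline omits
them from `table2.csv` with a logged note while keeping full diagnostics
in `gee_results.json`. Class-stratified models use independence working
correlation with robust SEs (as the source analyses did) and are
unaffected.

## 5. The synthetic world

The generator emulates the cohort a provincial administrative linkage
would yield:

- **Division populations** log-uniform between a configurable minimum and
  maximum (defaults 3,500 and 738,000, matching the published range of
  youth populations across 49 divisions); log-uniform mimics the heavy
  skew of real division sizes given only the extremes.
- **Division effect** $u_d = \exp(N(-\sigma^2/2, \sigma))$, one draw per
  division, applied multiplicatively to every class's rate; the
  $-\sigma^2/2$ correction keeps $E[u_d]=1$ so configured baselines stay
  interpretable as reference-pattern means. The default $\sigma = 0.99$
  was chosen so the expected SCV $100(e^{\sigma^2}-1) \approx 167$ matches
  the published overall SCV of 167.5. Worth noting: the published EQ
  (3.5) and CV (33.2%) would imply $\sigma \approx 0.3$ under the same
  log-normal model — the three published statistics are mutually
  inconsistent under any single multiplicative mixing law, and we
  calibrated to the SCV because it is the headline variation measure.
- **Covariate effects**: the published adjusted rate ratios (age, sex,
  rurality, income quintile, ADG band) are the default generative truth,
  per class, applied as $\exp(\sum \text{log-RR})$ on the rate scale. The
  cross-class "other psychotropic" effect is *not* generable — the four
  class draws are independent given covariates and $u_d$, since a mutual
  dependence would be circular — and configs requesting it are rejected.
- **Probabilities** are $\min(1, \text{baseline}/1000 \cdot u_d \cdot
  \exp(\cdot))$. Validation rejects any config whose most-exposed
  covariate pattern exceeds 1 before the division effect; clamping caused
  by extreme $u_d$ draws is reported as a message with the affected
  fraction (~0.01–2% of draws depending on the world). Note that
  "baseline" is the reference-pattern rate: with the published age effects
  (antidepressants at ages 20–24 carry RR 9.32) the *marginal* class
  prevalence exceeds the configured baseline by construction.
- **Sampling design**: non-recipients are down-sampled by taking every
  10th element of a random permutation, so the sum of emitted weights
  equals the simulated population up to the remainder modulo 10 (tested
  exactly).
- **Division covariates** are drawn independently of each other and of
  $u_d$ (the source gives no joint distribution), with
  Ontario-plausible families chosen once: log-normal for the three
  service-density/utilization measures (medians ≈ 3 per 100k, 0.15 per
  1k, 15 per 1k) and for the minority/non-citizen/language percentages;
  truncated normal for % post-secondary (55 ± 8), % employed (60 ± 5)
  and household size (2.6 ± 0.2). They have **no generative effect** on
  rates, so fitted division-covariate coefficients are known-null noise
  terms.
- **Prescription counts** per dispensed person-class are
  $1 + \text{NegBin}(\mu{=}2, \text{size}{=}2)$ (about 3 scripts/year),
  supporting the prescriptions numerator mode.
- All draws flow from one seeded RNG stream in a fixed documented order;
  identical (config, seed) pairs are byte-identical (tested).

### What the generator does *not* emulate

No dispensing dates or refill dynamics, no record-linkage artifacts, no
true cross-class treatment dependence, no spatial correlation between
neighbouring divisions, no correlation among division covariates or
between covariates and the division effect, and no ACG grouping logic
(ADG counts are drawn directly from a truncated negative binomial,
size 2, mean 4). A green test suite therefore establishes that the
*estimators* behave correctly in a world with the stated marginal
structure — not that the synthetic province reproduces every joint feature
of the real one.

## 6. Parameter recovery and its design choices

The stochastic acceptance checks generate the stated world (30 divisions,
~207,000 simulated persons per cohort, published effects as truth) over
20 seeds, refit the stratified class GEE, and require the mean recovered
male-stimulant RR (truth 1.75) and income-Q5 antipsychotic RR (truth
0.72) to land within 0.05. Two alignment decisions matter:

- The recovery model excludes the other-psychotropic-class covariate.
  Under the generator truth its coefficient is exactly null (classes are
  conditionally independent), but because it correlates with the
  *unmodelled* division effect $u_d$, including it lets it act as a proxy
  and measurably contaminates the sex coefficient (about +0.08 on the RR
  scale in our measurements). Fitting the model that matches the
  generative truth is the correct recovery check; the full published
  covariate set (including other-class) remains the pipeline default for
  data analysis.
- Division-level covariates stay in the recovery model as known-null
  terms; with 30 clusters they cost degrees of freedom but do not bias
  the individual-level coefficients.

## 7. Descriptives

Standardized differences use the two-proportion form
$|p_1-p_2|/\sqrt{(p_1(1-p_1)+p_2(1-p_2))/2}$ and the pooled-SD form for
means. Published baseline tables report medians/IQRs for age yet print a
standardized difference computable only from means and SDs; we do the
same — medians/IQRs for display, mean/SD for the standardized difference —
since the original recipe for skewed variables is unstated. Spearman
correlations use mid-ranks for ties and Fisher-z intervals with
$SE = 1/\sqrt{n-3}$; at $\rho = 0.52, n = 49$ this gives (0.28, 0.70)
where the source prints (0.27, 0.71), so the published interval came from
a different (unstated) recipe — we document the near-match rather than
assert equality.

## 8. Numerical and degenerate-input policy

Probability vectors must sum to 1 within 1e-9; expected counts must be
strictly positive for the SCV (the offending division is named); the EQ
refuses a zero minimum; standardized-difference and correlation functions
signal explicit `undefined` conditions rather than returning NaN; empty
subgroups are a signalled condition, never 0/0; unknown division IDs and
zero-population divisions are hard errors listing offenders; rank-deficient
designs name the aliased columns; zero-variance division covariates are
dropped with a warning, while a single-level individual covariate is a
hard error. Non-convergence of the GEE is a reported state carrying the
last iterate and exit update size — never a silent result.

## 9. Known limitations

- The cell-level exchangeable GEE is ill-posed under very strong
  area-level heterogeneity (Section 4); the package reports rather than
  repairs this. A size-aware working correlation (person-level
  exchangeability evaluated on aggregated cells) would be the natural
  extension.
- The published provincial quantities (overall standardized rate
  76.9/1000, CV 33.2, SCV 167.5, Spearman 0.52) require the restricted
  source data and are not reproducible here; the suite substitutes
  property-based checks (Poisson-null and mixing calibration of the SCV,
  GLM-oracle equivalence, CI coverage, standardization identities).
- Cells never observed in the 10% non-recipient sample are absent from
  the model table, which slightly biases small-cell Pearson residuals
  upward and inflates $\hat\phi$ and moment-$\hat\alpha$; covariate
  coefficient estimates are essentially unaffected (the recovery tests
  bound this empirically).
- One-year closed cohort; no time-at-risk adjustment, no spatial
  statistics, no causal interpretation.
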