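---
title: "Methods: family genetic risk, educational-attainment aptitude, and their interplay"
author: "gaeamod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family genetic risk, educational-attainment aptitude, and their interplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Registry-based psychiatric genetics can measure a person's inherited risk
for a disorder without any molecular data: the *family genetic risk score*
(FGRS) aggregates the affection status of 1st–5th-degree relatives under a
liability-threshold model. The same construction applied to relatives'
educational attainment yields a *genetic aptitude for educational
attainment* (GAEA). The questions this package operationalizes are (i) how
strongly GAEA correlates with disorder-specific genetic risk, (ii) how much
GAEA shifts disorder incidence on the additive-hazard scale once
disorder-specific risk is controlled, (iii) whether GAEA *moderates* the
effect of disorder-specific risk (an FGRS × GAEA interaction on the
additive scale), and (iv) how much of the GAEA effect in males is mediated
by conscript-measured IQ versus resilience.

Because the national registry data behind such analyses are confidential,
the package ships a synthetic-registry generator with the statistical
structure the analysis assumes, so that every stage is exercised and tested
end to end on data whose ground truth is known.

## The synthetic registry

**Pedigrees.** Each of `n_founder_couples` founds one family tree.
Descendants always marry unrelated "immigrant" founders, never within the
tree, so pedigrees are outbred by construction and each connected component
stays small (a few dozen members). With the default four generations, a
cohort member has identifiable relatives of every degree 1–5: parents and
siblings (degree 1), grandparents, aunts/uncles (2), first cousins and
great-grandparents (3), first cousins once removed (4), and second cousins
(5), averaging roughly 30 enumerable relatives per proband. This is a
deliberately scaled-down stand-in for real extended pedigrees (which
average ~40 relatives per proband); it preserves the degree structure the
scoring needs without attempting Swedish demography, immigration or
assortative mating.

**Genetics.** Additive genetic values for the ten disorder liabilities and
for educational attainment (EA) are drawn for founders from a multivariate
normal with variances equal to the trait heritabilities and covariances
`r_g * sqrt(h2_EA * h2_d)`; disorders are mutually uncorrelated beyond
their shared EA correlation, which keeps the correlation matrix positive
semi-definite for the default `r_g` vector (checked at configuration
time). Children receive the midparent mean plus Mendelian segregation
noise with half the additive variance, which preserves the variance and
covariance structure across generations. Liability adds independent
environmental noise to unit variance; affection is `liability >
qnorm(1 - K)` with sex-specific prevalences `K_f / K_m = sex_ratio` and
`(K_f + K_m)/2 = K`.

**Defaults as study conditions.** Lifetime prevalences (MD 17.66 %, AD
19.75 %, …, SZ 0.20 %) and EA genetic correlations (−0.29 for DUD through
+0.01 for BN) are the registry cohort values the package models.
Heritabilities and sex ratios are not reported alongside them, so the
defaults use familiar twin-study liability heritabilities (e.g. 0.35 for
MD, 0.80 for SZ) and registry sex ratios; they only need to be plausible
for the score construction to be exercised. All are configurable.

**Events and censoring.** Follow-up runs from age 17 (month 204) to first
registration, death, emigration, or the administrative end (December 2018,
with a mid-year birth convention). Death and emigration are small constant
per-year hazards (0.0005 and 0.002). Whether a person is *ever* affected
is decided by the liability threshold; the *registration age* of an
affected person still under follow-up is an exponential waiting time from
age 17 drawn conditional on preceding their censoring month (inverse-CDF
of the truncated exponential, default rate `log(10)/408` per month). The
conditional draw is what makes the realized lifetime prevalence match `K`:
an unconditional draw truncated by censoring would silently deflate
prevalence. Events are generated for *all* generations, not only the
study cohort, because the scores need parents' and grandparents' affection
status — exactly as the real registers cover relatives; the 1973–1995
birth-cohort restriction is applied at analysis time.

**Mediators.** For males, IQ and resilience load on the unit-variance EA
genetic factor (defaults 0.60 and 0.35) with unique noise, then are
z-standardized within birth year — mirroring how conscript scores are
standardized. Females carry missing mediators, which confines the
mediation module to males.

**Cohabitation.** Co-residence years are N(15, 3) truncated at zero for
1st-degree pairs and N(0.5, 1) truncated at zero for the enumerable
2nd-degree pairs (grandparental, avuncular). More distant kin are recorded
as never co-resident; generating their rows would require enumerating all
3rd–5th-degree pairs inside the generator and they essentially never
co-reside under the model anyway. The adjustment machinery is fully
exercised by the degree-1 class.

## Kinship and relative enumeration

Kinship uses the standard recursion `phi(i,j) = (phi(f_i,j) +
phi(m_i,j))/2` on the generationally later member, with `phi(i,i) = (1 +
phi(f_i,m_i))/2`; the batch path computes per-component kinship matrices
by the tabular method (parents processed before children, each row a
parent-row average). Degrees bin the relatedness `2*phi` to the nearest
power of two on the log2 scale — 0.5 → 1 through 0.03125 → 5 — so parent
and full sibling are both degree 1 and a first cousin degree 3. Relatives
whose relatedness falls between bins (possible only with inbred
user-supplied pedigrees; the generator is outbred) go to the nearest bin.
Tests verify the recursion against an independent gene-dropping oracle
(10^5 simulated meioses) and the batch enumeration against a brute-force
all-pairs filter.

## FGRS and GAEA scoring

For proband *p* with phenotyped relatives *r*:

- contribution `z_r`: for a disorder, the truncated-normal mean liability
  given affection status — `dnorm(tau)/K` if affected,
  `-dnorm(tau)/(1-K)` otherwise, with `tau = qnorm(1-K)`; for GAEA, the
  relative's continuous EA z-score (high = more attainment);
- prevalence `K` is estimated per relative birth year from the bundle
  (strata with fewer than 10 cases fall back to the pooled estimate),
  because thresholds should follow the secular trend in registration;
- cohabitation adjustment: within each degree class with at least 10
  links, `z_r` is residualized on co-residence years by least squares,
  recentered so the class mean is preserved;
- aggregation: `raw_p = sum(w_r z_r) / (sum(w_r) + lambda)` with `w_r =
  2*phi` — i.e. the relatedness-weighted mean contribution shrunk by
  `s = sum(w)/(sum(w)+lambda)`, so probands with little family
  information shrink toward the population mean; `lambda` defaults to 1;
- standardization to z within birth-year × county strata (degenerate
  strata of size one standardize to 0 with a warning).

The exact weighting and shrinkage constants used with real registry data
are not public; this family of choices (relatedness weights, ridge-style
shrinkage, stratified standardization) reproduces the published method's
structure and is fully testable: the score never uses the proband's own
phenotype, adding an affected 1st-degree relative can never lower a
disorder score, and on simulated data the score correlates positively
with true genetic liability, more strongly for probands with more
relatives. Relatives with missing phenotype contribute nothing — treating
missingness as health would bias scores downward in families lost to
follow-up.

## Correlations between scores

`score_correlation()` reports the product-moment correlation of the
continuous z-scores and, alternatively, a maximum-likelihood tetrachoric
correlation after a median split of each score. Both are reported in the
pipeline's table 1 because the dichotomization behind published
"tetrachoric" correlations of continuous scores is not reconstructible;
the two agree closely in practice (the median-split tetrachoric is a
consistent estimator of the latent correlation for bivariate-normal
scores). The tetrachoric MLE fixes thresholds at the observed margins and
maximizes the bivariate-normal cell likelihood by bounded scalar
optimization on (−1+1e−6, 1−1e−6); the bivariate rectangle probability is
computed by one-dimensional quadrature of `dnorm(x) * pnorm((rho*x - k) /
sqrt(1-rho^2))`, and the standard error comes from the numerical observed
information. A zero margin is an error unless the +0.5 continuity
correction is requested.

## Aalen additive hazards

The hazard is `lambda(t|x) = b0(t) + sum_j b_j(t) x_j` on the time scale
of months since age 17. At each distinct event time the increment of the
cumulative coefficient vector is the least-squares solution `dB =
(X'X)^-1 X'e` over the risk set, with tied events processed jointly in one
increment. The implementation accumulates risk-set cross-product matrices
by cumulative sums over subjects sorted by decreasing exit time, so a fit
costs one small solve per distinct event time. Rank-deficient increments
(e.g. once a covariate is constant in the shrinking risk set) are skipped
and logged, matching the estimator's definition; the covariate-free fit
equals the Nelson–Aalen estimator exactly, and the full fit matches an
independent reference implementation (`survival::aareg`) to 1e−8 in tests.

Summaries report `100 * B_j(T*)` at `T* = 408` months — the %-unit
increase in 34-year cases per SD of the covariate, 34 years being the
cohort's mean follow-up. `B(T*)` (the cumulative coefficient at the last
event time at or before 408 months) is used rather than a time-averaged
slope times 408, which would disagree with the cumulative-coefficient
convention. Confidence intervals use a seeded subject-level nonparametric
bootstrap (default 200 replicates) rather than the closed-form variance;
it is simpler to verify and adequate at desk scale, and full-table
pipeline runs leave it off by default (`n_boot = 0`) because they fit 40+
models. Prediction grids evaluate `x'B(T*)` over FGRS −3..3 at GAEA levels
−2..2 with sex and birth year at their sample means, clamping to [0, 1]
(linear hazards can stray outside) and logging when clamping occurs.

A structural point the tests rely on: under the liability-threshold
generator, 34-year risk is a convex function of the underlying liability
index for rare disorders, so when GAEA correlates *negatively* with
liability the additive-scale cross-partial of risk in (FGRS, GAEA) is
negative — the fan-shaped interaction emerges without any planted
interaction parameter, steepest risk slopes at low GAEA, exactly the
qualitative pattern expected for externalizing disorders.

## Mediation in males

The outcome is first registration at or after age 19 (pre-19 cases are
excluded); predictors are standardized on the analysis sample. Mediator
equations `m1 = a1 g`, `m2 = a2 g` are least squares; the outcome is a
probit regression `y* = c'g + b1 m1 + b2 m2 + e`, and all effects are
divided by the model-implied SD of the latent response, `sqrt(var(c'g +
b1 m1 + b2 m2) + 1)`. The published analysis used a weighted-least-squares
categorical path estimator; the probit latent-response standardization
used here is a documented approximation expected to agree in sign and
rough magnitude, not digit for digit. The payoff is an exactly additive
decomposition: total = direct + (a1 b1 + a2 b2)/sd, via-IQ% + via-res% =
100 before rounding, both asserted to 1e−10 on every fit. The IQ-versus-
resilience contrast uses a seeded percentile bootstrap over subjects of
`a1 b1 − a2 b2` (default 1000 replicates, at least 100), since the
original test statistic is unstated.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains simulate → links → scores → table 1 (prevalence +
correlations) → table 2 (Aalen models A1/A2/B/C, optionally sex- or
birth-cohort-stratified) → prediction grids → table 3 (male mediation),
writing CSVs, a JSON manifest with md5 content hashes and per-stage row
and dropped-record counts, and a run log. Every stochastic stage draws
from a named substream derived deterministically from the master seed, so
a rerun with the same configuration is hash-identical. A failing stage
aborts with the stage name and writes the partial manifest.

The package's reference desk scale is a cohort of about 100,000 probands
(`n_founder_couples = 9000`), which runs the full pipeline in about a
minute on one core and is the size used by the end-to-end tests and the
acceptance script; statistical property tests use cohorts of 3,000–60,000
and simulation sizes of 10^4–2×10^5 chosen so that each check's Monte
Carlo error is comfortably inside its tolerance.

## What passing tests do and do not show

The generator reproduces the *structure* the analysis assumes — liability
thresholds, pedigree transmission, configured genetic correlations,
registry-style censoring — not Swedish reality: no ICD coding, no
immigration or assortative mating, stylized onset and cohabitation models,
and disorder liabilities uncorrelated beyond EA (real comorbidity is far
richer). Consequently the synthetic estimates match published registry
coefficients only qualitatively (signs, orderings, rough magnitudes);
exact agreement is asserted only for worked-example arithmetic on
published summary tables. Mediation estimates additionally inherit the
probit-versus-WLS approximation, and FGRS-based interaction estimates are
attenuated relative to the true liability-scale interaction because the
scores are noisy proxies of genetic values.
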