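# gaeamod

Registry-style analysis of how the **genetic aptitude for educational
attainment (GAEA)** moderates disorder-specific **family genetic risk
(FGRS)** for ten psychiatric and substance-use disorders (MD, AD, OCD, AN,
BN, DUD, AUD, ADHD, BD, SZ), for researchers in psychiatric genetic
epidemiology who want a fully testable, open reimplementation of this
pipeline. National registry data of this kind are confidential, so the
package pairs the analysis machinery with a synthetic-registry generator
whose ground truth is known.

## What it computes

- **FGRS / GAEA scoring.** For each proband, relatives of degree 1–5
  (kinship φ from the standard pedigree recursion, relatedness 2φ)
  contribute liability z-scores under the liability-threshold model
  (threshold τ = Φ⁻¹(1−K); affected mean φ(τ)/K, unaffected mean
  −φ(τ)/(1−K)), cohabitation-adjusted, relatedness-weighted and shrunk:
  `raw = Σ wᵣzᵣ / (Σ wᵣ + λ)`, then z-standardized within birth-year ×
  county strata. GAEA uses relatives' continuous educational-attainment
  z-scores the same way.
- **Score correlations.** Product-moment and maximum-likelihood
  tetrachoric (median split, bivariate-normal cell likelihood).
- **Aalen additive hazards.** λ(t|x) = β₀(t) + Σ βⱼ(t)xⱼ from age 17 in
  months; least-squares increments ΔB(tₖ) = (Xₖ′Xₖ)⁻¹Xₖ′eₖ at each event
  time; models A1/A2/B/C culminating in an FGRS × GAEA interaction on the
  additive scale; effects reported as the %-unit increase in cases per 34
  years, 100·Bⱼ(408 months); prediction grids over FGRS at GAEA = −2…+2 SD.
- **Mediation (males).** Three-path probit model g → {IQ, resilience} →
  disorder, effects on the standardized latent-response scale, exact
  decomposition total = direct + via-IQ + via-resilience, and a bootstrap
  test of via-IQ vs via-resilience.

## Worked example

```r
library(gaeamod)
library(data.table)

cfg <- run_config(sim = sim_config(n_founder_couples = 2000L),
                  disorders = c("MD", "DUD", "AUD"),
                  mediation_disorders = c("DUD", "MD"),
                  seed = 1L, outdir = "demo_run")
manifest <- run_pipeline(cfg)

fread("demo_run/table1.csv")
#>    disorder cases cohort_n prevalence_pct corr_pm corr_pm_se corr_tetra
#> 1:       MD  4008    22950          17.46  -0.065     0.0066     -0.073
#> 2:      DUD  1292    22950           5.63  -0.198     0.0063     -0.224
#> 3:      AUD   844    22950           3.68  -0.136     0.0065     -0.159
```

A cohort of 22,950 synthetic probands shows the configured structure:
lifetime prevalences near their targets (MD 17.66 %, DUD 5.62 %) and
negative FGRS–GAEA score correlations for the externalizing disorders
(attenuated relative to the configured genetic correlations of −0.29 /
−0.28, because scores are noisy family-based proxies).

```r
fread("demo_run/table2.csv")[model == "C" & term %in%
                             c("FGRS", "GAEA", "FGRS:GAEA")]
#>    disorder model  sex cohort      term estimate
#> 1:       MD     C  all    all      FGRS  11.3790
#> 2:       MD     C  all    all      GAEA  -0.6083
#> 3:       MD     C  all    all FGRS:GAEA  -0.4762
#> 7:      AUD     C  all    all      FGRS   3.2899
#> 8:      AUD     C  all    all      GAEA  -1.0775
#> 9:      AUD     C  all    all FGRS:GAEA  -0.6960
```

One SD of FGRS adds ~3.3 AUD cases per 100 people over 34 years; one SD
of GAEA removes ~1.1; and the negative interaction (−0.70) is the
fan shape — disorder risk rises faster with genetic liability in people
with low GAEA. `demo_run/grids.csv` holds the corresponding predicted
34-year rates over FGRS −3…+3 at five GAEA levels.

```r
fread("demo_run/table3.csv")[, .(disorder, total, direct, indirect,
                                 prop_mediated)]
#>    disorder  total direct indirect prop_mediated
#> 1:      DUD -0.145 -0.111   -0.034          23.6
#> 2:       MD -0.065 -0.062   -0.003           4.8
```

In males, the GAEA effect on DUD risk is −0.145 on the latent-response
scale, 23.6 % of it mediated through IQ and resilience at this cohort
size (small-sample mediation estimates are noisy; at the reference desk
scale of ~100,000 probands the proportions stabilize).

At larger scale, rerunning with `sim_config(n_founder_couples = 9000L)`
reproduces the qualitative registry pattern: negative externalizing
FGRS–GAEA correlations, negative FGRS × GAEA interactions for DUD/AUD/MD,
and a majority-mediated GAEA effect for externalizing disorders.

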