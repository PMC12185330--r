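Package: gaeamod
Title: Genetic Aptitude for Educational Attainment as a Moderator of
    Family Genetic Risk for Psychiatric Disorders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates national-registry style cohorts with extended
    pedigrees, computes phenotype-based family genetic risk scores (FGRS)
    and a genetic aptitude for educational attainment (GAEA) score from
    1st-5th degree relatives under a liability-threshold model, estimates
    tetrachoric and product-moment correlations between genetic scores,
    fits Aalen additive-hazards models with an FGRS-by-GAEA interaction on
    the additive scale, and decomposes the GAEA effect on disorder risk
    into direct and IQ- or resilience-mediated paths with a probit path
    model. Includes an end-to-end pipeline producing registry-study style
    summary tables and prediction grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
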