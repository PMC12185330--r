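## Shared fixtures (built once per test run) and independent oracles.

library(data.table)

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## Small bundle: fast, used for structural checks.
small_bundle <- function() {
  fixture("small_bundle", function()
    simulate_population(sim_config(n_founder_couples = 200L, seed = 101L)))
}

## Medium bundle: cohort around 55k with >= 20k sibling pairs, used for the
## statistical-structure invariants and score-recovery properties.
medium_bundle <- function() {
  fixture("medium_bundle", function()
    simulate_population(sim_config(n_founder_couples = 5000L, seed = 202L)))
}

medium_scores <- function() {
  fixture("medium_scores", function() {
    b <- medium_bundle()
    pr <- cohort_ids(b)
    g <- pedigree_graph(b$pedigree)
    lk <- relative_links(g, pr, cohab = b$cohab)
    list(bundle = b, probands = pr, links = lk,
         scores = suppressWarnings(
           compute_all_scores(b, lk, probands = pr,
                              traits = c("DUD", "MD", "GAEA"))))
  })
}

## Assemble a registry bundle from hand-built tables.
make_bundle <- function(persons, pedigree, events = NULL, cohab = NULL,
                        cohort_range = c(1973L, 1995L)) {
  if (is.null(events))
    events <- data.table(id = integer(), disorder = character(),
                         age_months = integer())
  if (is.null(cohab))
    cohab <- data.table(id_a = integer(), id_b = integer(),
                        years = numeric())
  structure(list(persons = as.data.table(persons),
                 pedigree = as.data.table(pedigree),
                 events = as.data.table(events),
                 cohab = as.data.table(cohab), truth = NULL,
                 meta = list(cohort_range = cohort_range,
                             admin_end_year = 2018L)),
            class = "registry_bundle")
}

## Independent gene-dropping kinship oracle: founders get unique allele
## labels, every child inherits one random allele from each parent, and
## phi(i, j) is estimated as the mean probability that a random allele of i
## matches a random allele of j, averaged over n_drops replicate drops.
gene_drop_kinship <- function(pedigree, i, j, n_drops = 1e5) {
  ped <- as.data.table(pedigree)
  g <- pedigree_graph(ped)
  n <- length(g$id)
  A1 <- A2 <- matrix(0L, n_drops, n)
  next_allele <- 1L
  for (k in g$order) {
    f <- g$father[k]; m <- g$mother[k]
    if (is.na(f)) {
      A1[, k] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      A1[, k] <- ifelse(pick, A1[, f], A2[, f])
    }
    if (is.na(m)) {
      A2[, k] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- runif(n_drops) < 0.5
      A2[, k] <- ifelse(pick, A1[, m], A2[, m])
    }
  }
  pi <- match(i, g$id); pj <- match(j, g$id)
  mean((A1[, pi] == A1[, pj]) + (A1[, pi] == A2[, pj]) +
         (A2[, pi] == A1[, pj]) + (A2[, pi] == A2[, pj])) / 4
}

## Three-generation reference pedigree: grandparents 1-2, their children
## 3 (father) and 5 (aunt), spouses 4 and 6, grandchildren 7-8 (sibs) and
## 9 (first cousin).
three_gen_pedigree <- function() {
  data.table(
    id        = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
    father_id = c(NA, NA, 1L, NA, 1L, NA, 3L, 3L, 6L),
    mother_id = c(NA, NA, 2L, NA, 2L, NA, 4L, 4L, 5L))
}

## Survival data with a known additive hazard on covariates X (per-month
## scale), administratively censored at cens_months.
sim_additive_survival <- function(n, beta, X, cens_months = 500) {
  haz <- pmax(as.vector(X %*% beta), 1e-6)
  tt <- rexp(n, haz)
  time <- pmin(tt, cens_months)
  list(time = time, status = as.integer(tt <= cens_months), X = X)
}

## Mediation sample with planted standardized paths.
sim_mediation <- function(n, a1, b1, a2, b2, cprime = 0, k_case = 0.2) {
  g <- rnorm(n)
  m1 <- a1 * g + sqrt(max(1 - a1^2, 0.01)) * rnorm(n)
  m2 <- a2 * g + sqrt(max(1 - a2^2, 0.01)) * rnorm(n)
  ystar <- cprime * g + b1 * m1 + b2 * m2 + rnorm(n)
  y <- as.integer(ystar > quantile(ystar, 1 - k_case))
  inp <- data.table(id = seq_len(n), g = g, m1 = m1, m2 = m2, y = y)
  setattr(inp, "class", c("mediation_input", "data.table", "data.frame"))
  inp
}
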