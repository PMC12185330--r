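## Family genetic risk scores (FGRS) and the genetic aptitude for
## educational attainment (GAEA).
##
## A proband's score aggregates phenotypic evidence from 1st-5th-degree
## relatives: each relative contributes a liability z (truncated-normal
## mean under the liability-threshold model for disorders; the continuous
## EA z-score for GAEA), contributions are cohabitation-adjusted within
## degree class, weighted by relatedness 2*phi, shrunk toward zero when
## little family information is available, and finally z-standardized
## within birth-year x county strata.

#' Liability-threshold model for a disorder
#'
#' For lifetime prevalence K the liability threshold is
#' `tau = qnorm(1 - K)`; the expected liability of an affected relative is
#' the upper-truncated standard-normal mean `dnorm(tau) / K` and of an
#' unaffected relative the lower-truncated mean `-dnorm(tau) / (1 - K)`,
#' so the population mean contribution is exactly zero.
#'
#' @param prevalence K in (0, 1).
#' @return A `liability_model` list with K, tau, z_affected, z_unaffected.
#' @export
liability_model <- function(prevalence) {
  if (!is.numeric(prevalence) || any(!(prevalence > 0 & prevalence < 1)))
    stop("prevalence must be in (0, 1)")
  tau <- qnorm(1 - prevalence)
  structure(list(K = prevalence, tau = tau,
                 z_affected = dnorm(tau) / prevalence,
                 z_unaffected = -dnorm(tau) / (1 - prevalence)),
            class = "liability_model")
}

#' @export
print.liability_model <- function(x, ...) {
  cat("<liability_model> K =", format(x$K),
      " tau =", format(round(x$tau, 4)),
      " z+ =", format(round(x$z_affected, 4)),
      " z- =", format(round(x$z_unaffected, 4)), "\n")
  invisible(x)
}

#' Liability contribution of one relative
#'
#' @param model A [liability_model()] (vectorized over its K).
#' @param affected Logical (vectorized): is the relative affected?
#' @return Truncated-normal mean liability: `z_affected` where affected,
#'   `z_unaffected` otherwise.
#' @export
relative_contribution <- function(model, affected) {
  stopifnot(inherits(model, "liability_model"), is.logical(affected))
  ifelse(affected, model$z_affected, model$z_unaffected)
}

#' Scoring configuration
#'
#' @param lambda Shrinkage constant (>= 0): the raw score is
#'   `sum(w * z) / (sum(w) + lambda)`, i.e. the relatedness-weighted mean
#'   contribution shrunk by `s = sum(w) / (sum(w) + lambda)`.
#' @param cohab_adjust Residualize contributions on co-residence years
#'   within degree class before aggregation?
#' @param min_relatives Minimum links in a degree class for the
#'   cohabitation regression to be fitted (pass-through below it).
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(lambda = 1.0, cohab_adjust = TRUE,
                           min_relatives = 10L) {
  stopifnot(is.finite(lambda), lambda >= 0, min_relatives >= 2)
  structure(list(lambda = lambda, cohab_adjust = cohab_adjust,
                 min_relatives = as.integer(min_relatives)),
            class = "scoring_config")
}

#' Cohabitation adjustment of relative contributions
#'
#' Within each degree class with at least `min_n` links and non-constant
#' co-residence years, contributions are residualized on cohabitation years
#' by least squares and re-centered so the class mean contribution is
#' preserved. Removes the environmental inflation of resemblance between
#' relatives who lived together.
#'
#' @param z Relative contributions.
#' @param degree Degree class (1-5) per contribution.
#' @param cohab_years Co-residence years per contribution.
#' @param min_n Minimum class size to fit (default 10).
#' @return Adjusted contributions (same length and class means as `z`).
#' @export
cohabitation_adjust <- function(z, degree, cohab_years, min_n = 10L) {
  stopifnot(length(z) == length(degree), length(z) == length(cohab_years))
  out <- z
  for (d in unique(degree)) {
    idx <- which(degree == d)
    if (length(idx) < min_n) next
    x <- cohab_years[idx]
    vx <- var(x)
    if (!is.finite(vx) || vx == 0) next
    xc <- x - mean(x)
    b <- sum(xc * z[idx]) / sum(xc^2)
    out[idx] <- z[idx] - b * xc   # recentering is implicit: mean(xc) = 0
  }
  out
}

## Per-birth-year prevalence of a disorder, floored: strata with fewer than
## `floor_cases` affected fall back to the pooled prevalence.
.prevalence_by_yob <- function(persons, events, disorder, floor_cases = 10L) {
  aff_ids <- unique(events[disorder, on = "disorder"]$id)
  aff <- persons$id %in% aff_ids
  K_all <- mean(aff)
  dt <- data.table(yob = persons$yob, aff = aff)
  st <- dt[, .(K = mean(aff), cases = sum(aff)), by = yob]
  st[cases < floor_cases, K := K_all]
  ## guard: prevalence must stay inside (0, 1) for the threshold model
  st[, K := pmin(pmax(K, 1e-6), 1 - 1e-6)]
  st
}

#' Compute FGRS or GAEA scores for a set of probands
#'
#' For a disorder trait each phenotyped relative contributes the
#' liability-threshold mean given their affection status, with the
#' prevalence estimated per relative birth year from the bundle (strata
#' with fewer than 10 cases fall back to the pooled prevalence) unless a
#' single [liability_model()] is supplied. For trait `"GAEA"` relatives
#' contribute their continuous EA z-score directly (high = more
#' attainment). Contributions are cohabitation-adjusted, weighted by
#' relatedness `2 * phi`, shrunk by `sum(w) / (sum(w) + lambda)`, and
#' standardized within birth-year x county strata of the probands.
#' The proband's own phenotype is never used.
#'
#' @param bundle A `registry_bundle`.
#' @param links Relative links from [relative_links()].
#' @param trait A disorder code or `"GAEA"`.
#' @param model Optional [liability_model()] overriding the per-birth-year
#'   prevalence estimate (disorder traits only).
#' @param config A [scoring_config()].
#' @param probands Proband ids to score (default: every proband appearing
#'   in `links`); probands without phenotyped relatives get raw score 0.
#' @return data.table(id, trait, raw, weight_sum, z) of class
#'   `genetic_scores`.
#' @export
compute_fgrs <- function(bundle, links, trait, model = NULL,
                         config = scoring_config(),
                         probands = NULL) {
  stopifnot(inherits(bundle, "registry_bundle"),
            inherits(config, "scoring_config"))
  persons <- bundle$persons
  if (nrow(persons) == 0L) stop("empty cohort: no persons in bundle")
  if (is.null(probands)) probands <- sort(unique(links$proband))
  lk <- as.data.table(links)[proband %in% probands]

  ## contribution of each linked relative
  if (identical(trait, "GAEA")) {
    ea <- setNames(persons$ea_z, persons$id)
    contrib <- ea[as.character(lk$relative)]
  } else {
    if (!trait %in% unique(c(DISORDER_CODES, bundle$events$disorder)))
      stop("unknown trait: ", trait)
    aff_ids <- unique(bundle$events[disorder == trait, id])
    aff <- lk$relative %in% aff_ids
    if (is.null(model)) {
      st <- .prevalence_by_yob(persons, bundle$events, trait)
      yob_lookup <- setNames(persons$yob, persons$id)
      Krel <- st[data.table(yob = yob_lookup[as.character(lk$relative)]),
                 K, on = "yob"]
      lm_rel <- liability_model(Krel)
    } else {
      stopifnot(inherits(model, "liability_model"))
      lm_rel <- model
    }
    contrib <- relative_contribution(lm_rel, aff)
  }

  ## relatives with unknown phenotype contribute nothing
  keep <- !is.na(contrib)
  lk <- lk[keep]
  contrib <- contrib[keep]

  if (isTRUE(config$cohab_adjust) && nrow(lk))
    contrib <- cohabitation_adjust(contrib, lk$degree, lk$cohab_years,
                                   min_n = config$min_relatives)

  w <- lk$relatedness
  agg <- data.table(proband = lk$proband, wz = w * contrib, w = w)[
    , .(sw_z = sum(wz), sw = sum(w)), by = proband]
  scores <- data.table(id = probands)
  scores[agg, `:=`(sw_z = i.sw_z, sw = i.sw), on = c(id = "proband")]
  scores[is.na(sw), `:=`(sw_z = 0, sw = 0)]
  scores[, raw := ifelse(sw + config$lambda > 0,
                         sw_z / (sw + config$lambda),
                         0)]
  scores[, weight_sum := sw]
  scores[, c("sw_z", "sw") := NULL]

  ## standardize within birth-year x county strata of the probands
  pinfo <- persons[, .(id, yob, county)]
  scores <- pinfo[scores, on = "id"]
  scores[, stratum := paste(yob, county, sep = ":")]
  singles <- scores[, .N, by = stratum][N == 1L, stratum]
  if (length(singles))
    warning(length(singles),
            " stratum/strata of size 1: standardized score set to 0")
  scores[, z := .z_by_stratum(raw, stratum)]
  out <- scores[, .(id, trait = trait, raw, weight_sum, z)]
  setorder(out, id)
  setattr(out, "class", c("genetic_scores", class(out)))
  out[]
}

#' Score every disorder plus GAEA
#'
#' Convenience wrapper returning one long table of standardized scores.
#'
#' @inheritParams compute_fgrs
#' @param traits Traits to score (default all ten disorders and GAEA).
#' @return data.table(id, trait, raw, weight_sum, z).
#' @export
compute_all_scores <- function(bundle, links, config = scoring_config(),
                               probands = NULL,
                               traits = c(DISORDER_CODES, "GAEA")) {
  rbindlist(lapply(traits, function(tr)
    compute_fgrs(bundle, links, tr, config = config, probands = probands)))
}
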