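## Synthetic national-registry population generator.
##
## The generator emulates the statistical structure a registry-based
## FGRS/GAEA analysis assumes: multigenerational outbred pedigrees, additive
## polygenic liabilities for ten disorders and for educational attainment
## (EA) transmitted as midparent mean plus Mendelian segregation noise,
## liability-threshold affection with sex-specific thresholds, onset ages
## within registry follow-up, censoring by death/emigration/administrative
## end, male-only conscript mediators (IQ, resilience), and co-residence
## years used by the cohabitation adjustment.

#' Specify one disorder for the registry simulator
#'
#' @param code Disorder code, one of [DISORDER_CODES].
#' @param prevalence Lifetime prevalence in (0, 1).
#' @param heritability Proportion of liability variance that is additive
#'   genetic, in (0, 1).
#' @param onset_rate Exponential rate (per month from age 17) of the
#'   age-at-first-registration model. The onset age is drawn conditional on
#'   preceding the person's censoring month, so the realized lifetime
#'   prevalence matches `prevalence`.
#' @param sex_ratio Female:male prevalence ratio (1 = no sex difference).
#' @return A `disorder_spec` list.
#' @export
disorder_spec <- function(code, prevalence, heritability,
                          onset_rate = log(10) / 408, sex_ratio = 1) {
  stopifnot(is.character(code), length(code) == 1L)
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence for ", code, " must be in (0, 1)")
  if (!(heritability >= 0 && heritability < 1))
    stop("heritability for ", code, " must be in [0, 1)")
  stopifnot(onset_rate > 0, sex_ratio > 0)
  structure(list(code = code, prevalence = prevalence,
                 heritability = heritability, onset_rate = onset_rate,
                 sex_ratio = sex_ratio),
            class = "disorder_spec")
}

#' Default disorder specifications
#'
#' Lifetime prevalences (0.20\% for SZ up to 19.75\% for AD) follow the
#' registry cohort the package models; heritabilities and sex ratios are
#' field-standard stand-ins (twin-study liability heritabilities, registry
#' sex ratios) since the score construction only needs plausible values.
#'
#' @return Named list of [disorder_spec()] objects, one per disorder.
#' @export
default_disorder_specs <- function() {
  tab <- data.frame(
    code = DISORDER_CODES,
    prevalence = c(0.1766, 0.1975, 0.0130, 0.0050, 0.0032,
                   0.0562, 0.0379, 0.0332, 0.0146, 0.0020),
    heritability = c(0.35, 0.30, 0.45, 0.55, 0.50,
                     0.55, 0.50, 0.70, 0.80, 0.80),
    sex_ratio = c(1.7, 1.8, 1.1, 9.0, 9.0,
                  0.50, 0.45, 0.45, 1.1, 0.8)
  )
  specs <- lapply(seq_len(nrow(tab)), function(i)
    disorder_spec(tab$code[i], tab$prevalence[i], tab$heritability[i],
                  sex_ratio = tab$sex_ratio[i]))
  names(specs) <- tab$code
  specs
}

#' Default genetic correlations between EA and disorder liabilities
#'
#' The genetic correlation of each disorder liability with the additive
#' genetic value for educational attainment: moderate and negative for
#' externalizing disorders (-0.27 to -0.29), modest and negative for
#' internalizing disorders, near zero for eating/compulsive and psychotic
#' disorders (slightly positive for BN).
#'
#' @return Named numeric vector over [DISORDER_CODES].
#' @export
default_rg_ea <- function() {
  c(MD = -0.10, AD = -0.15, OCD = 0.00, AN = -0.03, BN = 0.01,
    DUD = -0.29, AUD = -0.28, ADHD = -0.27, BD = -0.04, SZ = -0.01)
}

#' Configure the registry simulator
#'
#' @param n_founder_couples Number of founder couples; each founds one
#'   family tree whose descendants marry in unrelated immigrant founders,
#'   so pedigrees stay outbred and components stay small.
#' @param n_generations Number of generations (at least 3; default 4, which
#'   gives probands identifiable 1st-5th-degree relatives including second
#'   cousins).
#' @param birth_year_range Two-element integer vector, the birth cohort of
#'   the study (default 1973-1995). Earlier generations are placed 20 years
#'   apart.
#' @param disorder_specs List of [disorder_spec()] (default
#'   [default_disorder_specs()]).
#' @param gaea_spec List with `h2_ea` (heritability of EA, in (0,1)) and
#'   `r_g` (named vector of genetic correlations between EA and each
#'   disorder liability; default [default_rg_ea()]).
#' @param mediator_spec List with `iq_loading` and `res_loading`: loadings
#'   of the conscript IQ and resilience scores on the unit-variance EA
#'   genetic factor; unique variance makes each mediator unit variance.
#' @param censoring List with per-year `death_hazard` and `emig_hazard` and
#'   `admin_end_year` (default Dec 2018).
#' @param cohabitation_model List with `deg1` = c(mean, sd) of co-residence
#'   years for 1st-degree relatives and `other` = c(mean, sd) for closer
#'   enumerated kin; both truncated at 0.
#' @param mean_children Mean number of children per couple (Poisson).
#' @param p_marry Probability a non-terminal-generation member marries an
#'   immigrant founder and reproduces.
#' @param n_counties Number of synthetic county labels (standardization
#'   strata).
#' @param seed Integer master seed; fully determines the simulated bundle.
#' @return A `sim_config` list, validated (positive semi-definite genetic
#'   correlation structure, prevalences in (0,1)).
#' @export
sim_config <- function(n_founder_couples = 500L,
                       n_generations = 4L,
                       birth_year_range = c(1973L, 1995L),
                       disorder_specs = default_disorder_specs(),
                       gaea_spec = list(h2_ea = 0.40, r_g = default_rg_ea()),
                       mediator_spec = list(iq_loading = 0.60,
                                            res_loading = 0.35),
                       censoring = list(death_hazard = 0.0005,
                                        emig_hazard = 0.002,
                                        admin_end_year = 2018L),
                       cohabitation_model = list(deg1 = c(15, 3),
                                                 other = c(0.5, 1)),
                       mean_children = 2.3,
                       p_marry = 0.9,
                       n_counties = 5L,
                       seed = 1L) {
  stopifnot(n_founder_couples >= 1, length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2],
            mean_children > 0, p_marry >= 0, p_marry <= 1, n_counties >= 1)
  if (n_generations < 3)
    stop("n_generations must be at least 3")
  codes <- vapply(disorder_specs, function(s) s$code, "")
  if (anyDuplicated(codes)) stop("duplicate disorder codes")
  names(disorder_specs) <- codes
  h2_ea <- gaea_spec$h2_ea
  if (!(h2_ea >= 0 && h2_ea < 1)) stop("h2_ea must be in [0, 1)")
  r_g <- gaea_spec$r_g
  if (is.null(names(r_g)) || !all(codes %in% names(r_g)))
    stop("gaea_spec$r_g must be named for every disorder code")
  r_g <- r_g[codes]
  ## Genetic correlation matrix: disorders mutually uncorrelated, EA
  ## correlated with each disorder by r_g.  Must be positive semi-definite.
  p <- length(codes) + 1L
  R <- diag(p)
  R[p, seq_along(codes)] <- R[seq_along(codes), p] <- r_g
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    worst <- codes[which.max(abs(r_g))]
    stop("genetic correlation matrix is not positive semi-definite; ",
         "largest offending correlation is EA-", worst, " = ",
         format(r_g[which.max(abs(r_g))]))
  }
  structure(list(n_founder_couples = as.integer(n_founder_couples),
                 n_generations = as.integer(n_generations),
                 birth_year_range = as.integer(birth_year_range),
                 disorder_specs = disorder_specs,
                 gaea_spec = list(h2_ea = h2_ea, r_g = r_g),
                 mediator_spec = mediator_spec,
                 censoring = censoring,
                 cohabitation_model = cohabitation_model,
                 mean_children = mean_children,
                 p_marry = p_marry,
                 n_counties = as.integer(n_counties),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## Matrix square root tolerant of zero variance (h2 = 0 edge cases).
.mat_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S))
}

## z-standardize x within strata; degenerate strata (size 1 or zero
## variance) map to 0.
.z_by_stratum <- function(x, stratum) {
  dt <- data.table(x = x, s = stratum)
  dt[, zz := {
    if (.N < 2L) rep(0, .N) else {
      sdv <- sd(x)
      if (!is.finite(sdv) || sdv == 0) rep(0, .N) else (x - mean(x)) / sdv
    }
  }, by = s]
  dt$zz
}

#' Simulate a synthetic registry population
#'
#' Builds a multigenerational pedigree (one family tree per founder couple;
#' spouses are unrelated immigrant founders), draws additive genetic values
#' for the ten disorder liabilities and EA from a multivariate normal with
#' the configured heritabilities and EA genetic correlations, transmits them
#' as midparent mean plus segregation noise with half the additive variance,
#' converts liabilities to affection by the liability-threshold rule with
#' sex-specific thresholds, assigns onset ages (censoring-truncated
#' exponential waiting times from age 17), simulates death/emigration
#' censoring, the EA phenotype, male conscript mediators standardized
#' within birth year, and co-residence years.
#'
#' @param config A [sim_config()].
#' @return A `registry_bundle`: list with data.tables `persons` (id, sex,
#'   yob, county, death_month, emig_month, ea_z, iq_z, res_z), `pedigree`
#'   (id, father_id, mother_id), `events` (id, disorder, age_months),
#'   `cohab` (id_a, id_b, years), plus `truth` (per-person true genetic
#'   values and liabilities; simulation diagnostic, not part of the on-disk
#'   schema) and `meta`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "simulate"))

  specs <- config$disorder_specs
  codes <- names(specs)
  K <- vapply(specs, function(s) s$prevalence, 0)
  h2 <- vapply(specs, function(s) s$heritability, 0)
  onset_rate <- vapply(specs, function(s) s$onset_rate, 0)
  sex_ratio <- vapply(specs, function(s) s$sex_ratio, 0)
  h2_ea <- config$gaea_spec$h2_ea
  r_g <- config$gaea_spec$r_g
  traits <- c(codes, "EA")
  p <- length(traits)

  Sg <- diag(c(h2, h2_ea), p)
  Sg[p, seq_along(codes)] <- Sg[seq_along(codes), p] <-
    r_g * sqrt(h2_ea * h2)
  dimnames(Sg) <- list(traits, traits)
  M_founder <- .mat_sqrt(Sg)
  M_seg <- M_founder / sqrt(2)
  draw_founder <- function(n)
    matrix(rnorm(n * p), n, p) %*% t(M_founder)
  draw_seg <- function(n)
    matrix(rnorm(n * p), n, p) %*% t(M_seg)

  Gn <- config$n_generations
  yr <- config$birth_year_range
  windows <- lapply(seq_len(Gn), function(g) yr - (Gn - g) * 20L)

  ## ---- pedigree construction, generation by generation -------------------
  F0 <- config$n_founder_couples
  n1 <- 2L * F0
  ids <- seq_len(n1)
  father <- rep(NA_integer_, n1)
  mother <- rep(NA_integer_, n1)
  sexv <- rep(c("M", "F"), F0)
  w1 <- windows[[1L]]
  yobv <- sample(seq(w1[1], w1[2]), n1, replace = TRUE)
  genv <- rep(1L, n1)
  Gmat <- draw_founder(n1)
  colnames(Gmat) <- traits
  couples <- data.table(fid = ids[sexv == "M"], mid = ids[sexv == "F"])

  for (g in seq(2L, Gn)) {
    if (nrow(couples) == 0L) break
    nk <- rpois(nrow(couples), config$mean_children)
    fa <- rep(couples$fid, nk)
    mo <- rep(couples$mid, nk)
    nc <- length(fa)
    if (nc == 0L) { couples <- couples[0L]; next }
    w <- windows[[g]]
    yb <- sample(seq(w[1], w[2]), nc, replace = TRUE)
    yb <- pmin(pmax(yb, pmax(yobv[fa], yobv[mo]) + 18L), w[2])
    sx <- sample(c("M", "F"), nc, replace = TRUE)
    cid <- length(ids) + seq_len(nc)
    gv <- (Gmat[fa, , drop = FALSE] + Gmat[mo, , drop = FALSE]) / 2 +
      draw_seg(nc)
    ids <- c(ids, cid)
    father <- c(father, fa)
    mother <- c(mother, mo)
    sexv <- c(sexv, sx)
    yobv <- c(yobv, yb)
    genv <- c(genv, rep(g, nc))
    Gmat <- rbind(Gmat, gv)

    if (g < Gn) {
      marry <- runif(nc) < config$p_marry
      nm <- sum(marry)
      if (nm > 0L) {
        sid <- length(ids) + seq_len(nm)
        ssx <- ifelse(sx[marry] == "M", "F", "M")
        syb <- sample(seq(w[1], w[2]), nm, replace = TRUE)
        ids <- c(ids, sid)
        father <- c(father, rep(NA_integer_, nm))
        mother <- c(mother, rep(NA_integer_, nm))
        sexv <- c(sexv, ssx)
        yobv <- c(yobv, syb)
        genv <- c(genv, rep(g, nm))
        Gmat <- rbind(Gmat, draw_founder(nm))
        mc <- cid[marry]
        couples <- data.table(
          fid = ifelse(sx[marry] == "M", mc, sid),
          mid = ifelse(sx[marry] == "M", sid, mc))
      } else couples <- couples[0L]
    }
  }

  n <- length(ids)
  county <- sample(paste0("C", seq_len(config$n_counties)), n, replace = TRUE)

  ## ---- censoring ---------------------------------------------------------
  draw_cens <- function(hazard) {
    if (is.null(hazard) || hazard <= 0) return(rep(NA_integer_, n))
    yrs <- rgeom(n, hazard)
    as.integer(yrs * 12L + sample.int(12L, n, replace = TRUE) - 1L)
  }
  admin_end <- config$censoring$admin_end_year
  admin <- (admin_end - yobv) * 12L + 6L
  death_month <- draw_cens(config$censoring$death_hazard)
  emig_month <- draw_cens(config$censoring$emig_hazard)
  ## only censoring observed before the administrative end is on record
  death_month[!is.na(death_month) & death_month >= admin] <- NA_integer_
  ## emigration cannot follow death
  emig_month[!is.na(emig_month) &
               (emig_month >= admin |
                  (!is.na(death_month) & emig_month >= death_month))] <-
    NA_integer_
  censor <- pmin(admin,
                 ifelse(is.na(death_month), Inf, death_month),
                 ifelse(is.na(emig_month), Inf, emig_month))

  ## ---- liabilities, affection, onsets ------------------------------------
  E <- matrix(rnorm(n * p), n, p) %*%
    diag(sqrt(pmax(1 - c(h2, h2_ea), 0)), p)
  L <- Gmat + E
  colnames(L) <- traits
  is_f <- sexv == "F"
  ## sex-specific thresholds: K_f / K_m = sex_ratio, (K_f + K_m)/2 = K
  K_m <- pmin(2 * K / (1 + sex_ratio), 0.999)
  K_f <- pmin(sex_ratio * K_m, 0.999)
  events <- vector("list", length(codes))
  affected_mat <- matrix(FALSE, n, length(codes),
                         dimnames = list(NULL, codes))
  start <- FOLLOWUP_START_MONTHS
  for (d in seq_along(codes)) {
    tau <- ifelse(is_f, qnorm(1 - K_f[d]), qnorm(1 - K_m[d]))
    aff <- L[, d] > tau
    affected_mat[, d] <- aff
    idx <- which(aff & censor > start)
    if (length(idx)) {
      Tm <- censor[idx] - start
      r <- onset_rate[d]
      ## inverse-CDF draw from Exp(r) truncated at the censoring time, so
      ## every affected person still under follow-up registers in-window
      u <- runif(length(idx))
      t <- -log(1 - u * (1 - exp(-r * Tm))) / r
      events[[d]] <- data.table(id = ids[idx], disorder = codes[d],
                                age_months = start + as.integer(floor(t)) + 1L)
    }
  }
  events <- rbindlist(events)
  if (nrow(events) == 0L)
    events <- data.table(id = integer(), disorder = character(),
                         age_months = integer())
  setorder(events, id, disorder)

  ## ---- EA phenotype and conscript mediators ------------------------------
  ea_raw <- L[, "EA"]
  ea_z <- .z_by_stratum(ea_raw, yobv)
  f_ea <- if (h2_ea > 0) Gmat[, p] / sqrt(h2_ea) else rep(0, n)
  a_iq <- config$mediator_spec$iq_loading
  a_res <- config$mediator_spec$res_loading
  iq_z <- res_z <- rep(NA_real_, n)
  m <- which(!is_f)
  if (length(m)) {
    iq_raw <- a_iq * f_ea[m] + sqrt(max(1 - a_iq^2, 0)) * rnorm(length(m))
    res_raw <- a_res * f_ea[m] + sqrt(max(1 - a_res^2, 0)) * rnorm(length(m))
    iq_z[m] <- .z_by_stratum(iq_raw, yobv[m])
    res_z[m] <- .z_by_stratum(res_raw, yobv[m])
  }

  persons <- data.table(id = ids, sex = sexv, yob = yobv, county = county,
                        death_month = death_month, emig_month = emig_month,
                        ea_z = ea_z, iq_z = iq_z, res_z = res_z)
  pedigree <- data.table(id = ids, father_id = father, mother_id = mother)

  cohab <- .simulate_cohab(pedigree, config$cohabitation_model)

  truth <- data.table(id = ids)
  for (tr in traits) truth[[paste0("g_", tr)]] <- Gmat[, tr]
  for (d in codes) truth[[paste0("liab_", d)]] <- L[, d]
  truth$generation <- genv

  structure(list(persons = persons, pedigree = pedigree, events = events,
                 cohab = cohab, truth = truth,
                 meta = list(cohort_range = yr, seed = config$seed,
                             admin_end_year = admin_end)),
            class = "registry_bundle")
}

## Co-residence years for 1st-degree pairs (parent-child, full sibs) and the
## readily enumerable 2nd-degree pairs (grandparental, avuncular).  More
## distant kin are assumed never co-resident (0 years at scoring).
.simulate_cohab <- function(pedigree, model) {
  ped <- as.data.table(pedigree)
  n_max <- max(ped$id)
  fa <- mo <- rep(NA_integer_, n_max)
  fa[ped$id] <- ped$father_id
  mo[ped$id] <- ped$mother_id

  pc <- rbind(
    ped[!is.na(father_id), .(id_a = father_id, id_b = id)],
    ped[!is.na(mother_id), .(id_a = mother_id, id_b = id)])
  kids <- ped[!is.na(father_id) & !is.na(mother_id)]
  sib <- kids[kids, on = c("father_id", "mother_id"),
              allow.cartesian = TRUE][id < i.id, .(id_a = id, id_b = i.id)]
  deg1 <- rbind(pc, sib)

  gp <- rbind(
    data.table(id_a = fa[fa[ped$id]], id_b = ped$id),
    data.table(id_a = mo[fa[ped$id]], id_b = ped$id),
    data.table(id_a = fa[mo[ped$id]], id_b = ped$id),
    data.table(id_a = mo[mo[ped$id]], id_b = ped$id))
  gp <- gp[!is.na(id_a)]
  sib2 <- rbind(sib[, .(parent = id_a, unc = id_b)],
                sib[, .(parent = id_b, unc = id_a)])
  kid_by_parent <- rbind(
    ped[!is.na(father_id), .(parent = father_id, child = id)],
    ped[!is.na(mother_id), .(parent = mother_id, child = id)])
  av <- merge(sib2, kid_by_parent, by = "parent",
              allow.cartesian = TRUE)[, .(id_a = unc, id_b = child)]
  deg2 <- rbind(gp, av)

  out <- rbind(
    deg1[, .(id_a, id_b,
             years = pmax(0, rnorm(.N, model$deg1[1], model$deg1[2])))],
    deg2[, .(id_a, id_b,
             years = pmax(0, rnorm(.N, model$other[1], model$other[2])))])
  ## canonical unordered pair order
  out[, `:=`(lo = pmin(id_a, id_b), hi = pmax(id_a, id_b))]
  out <- unique(out, by = c("lo", "hi"))
  res <- out[, .(id_a = lo, id_b = hi, years = years)]
  setorder(res, id_a, id_b)
  res
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("<registry_bundle>\n")
  cat("  persons:  ", nrow(x$persons), "\n")
  cat("  pedigree: ", nrow(x$pedigree), " (",
      sum(is.na(x$pedigree$father_id)), " founders)\n", sep = "")
  cat("  events:   ", nrow(x$events), "\n")
  cat("  cohab:    ", nrow(x$cohab), " pairs\n", sep = "")
  if (!is.null(x$meta$cohort_range))
    cat("  cohort:   born ", x$meta$cohort_range[1], "-",
        x$meta$cohort_range[2], "\n", sep = "")
  invisible(x)
}

#' Ids of cohort members (study probands)
#'
#' @param bundle A `registry_bundle`.
#' @param cohort_range Optional two-element birth-year range; defaults to
#'   the bundle's own cohort range (or all persons if unknown).
#' @return Integer vector of person ids.
#' @export
cohort_ids <- function(bundle, cohort_range = NULL) {
  if (is.null(cohort_range)) cohort_range <- bundle$meta$cohort_range
  if (is.null(cohort_range)) return(bundle$persons$id)
  bundle$persons[yob >= cohort_range[1] & yob <= cohort_range[2], id]
}
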