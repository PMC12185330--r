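## Mediation of the GAEA effect on disorder risk through IQ and resilience.
##
## Males only (the conscript register supplies the mediators).  A three-path
## model: GAEA -> disorder (direct), GAEA -> IQ -> disorder and
## GAEA -> resilience -> disorder.  Mediator equations are least squares;
## the binary outcome (first registration at or after age 19) is a probit
## regression, and all effects are reported on the standardized
## latent-response scale (coefficients divided by the model-implied SD of
## the latent outcome), so the decomposition total = direct + indirect is
## exact by construction.

#' Assemble the male mediation analysis sample
#'
#' Subjects: males with non-missing GAEA score, IQ and resilience z-scores.
#' Outcome: first registration for the disorder at or after age 19 (228
#' months); subjects registered before 19 are excluded. All predictors are
#' re-standardized on the analysis sample.
#'
#' @param bundle A `registry_bundle`.
#' @param gaea_scores `genetic_scores` for trait `"GAEA"` (id, z).
#' @param disorder Disorder code.
#' @param age_cut_months Outcome age cut (default 228 = 19 years).
#' @return A `mediation_input` data.table (id, g, m1, m2, y) with
#'   attributes `n_excluded` (pre-19 cases) and `disorder`.
#' @export
mediation_input <- function(bundle, gaea_scores, disorder,
                            age_cut_months = 228L) {
  stopifnot(inherits(bundle, "registry_bundle"))
  sc <- as.data.table(gaea_scores)
  males <- bundle$persons[sex == "M", .(id, iq_z, res_z)]
  d <- merge(males, sc[, .(id, g = z)], by = "id")
  ev <- bundle$events[disorder, on = "disorder", .(id, age_months),
                      nomatch = NULL]
  d[, ev_age := NA_integer_]
  if (nrow(ev)) d[ev, ev_age := i.age_months, on = "id"]
  n0 <- nrow(d)
  d <- d[is.na(ev_age) | ev_age >= age_cut_months]
  n_excluded <- n0 - nrow(d)
  d <- d[complete.cases(d[, .(g, iq_z, res_z)])]
  d[, y := as.integer(!is.na(ev_age))]
  zstd <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  out <- d[, .(id, g = zstd(g), m1 = zstd(iq_z), m2 = zstd(res_z), y)]
  setattr(out, "class", c("mediation_input", class(out)))
  setattr(out, "n_excluded", n_excluded)
  setattr(out, "disorder", disorder)
  out[]
}

## Internal path fit without sample-size guards (used by the bootstrap).
.fit_paths_core <- function(g, m1, m2, y) {
  a1 <- sum(g * m1) / sum(g * g)
  a2 <- sum(g * m2) / sum(g * g)
  fit <- suppressWarnings(
    glm(y ~ g + m1 + m2, family = binomial(link = "probit")))
  if (!fit$converged)
    stop("probit outcome model did not converge after ", fit$iter,
         " iterations")
  cf <- coef(fit)
  cp <- cf["g"]; b1 <- cf["m1"]; b2 <- cf["m2"]
  eta <- cp * g + b1 * m1 + b2 * m2
  sd_ystar <- sqrt(var(eta) + 1)   # probit latent residual variance is 1
  direct <- unname(cp / sd_ystar)
  ind_iq <- unname(a1 * b1 / sd_ystar)
  ind_res <- unname(a2 * b2 / sd_ystar)
  indirect <- ind_iq + ind_res
  total <- direct + indirect
  list(total = total, direct = direct, indirect = indirect,
       ind_iq = ind_iq, ind_res = ind_res,
       a1 = a1, a2 = a2,
       b1 = unname(b1 / sd_ystar), b2 = unname(b2 / sd_ystar))
}

#' Fit the three-path mediation model
#'
#' Mediator equations `m1 = a1 g + e1`, `m2 = a2 g + e2` by least squares;
#' outcome by probit regression `y* = c' g + b1 m1 + b2 m2 + e`; effects
#' standardized to the latent-response scale and assembled by
#' product-of-coefficients. `total = direct + indirect` holds exactly, and
#' the via-IQ and via-resilience percentages sum to 100 on unrounded
#' values.
#'
#' @param input A [mediation_input()].
#' @param min_n Minimum sample size (default 500).
#' @param min_cases Minimum outcome cases (default 20).
#' @return A `mediation_fit`: effects (total, direct, indirect, via IQ,
#'   via resilience), proportion statistics (in percent), path
#'   coefficients, n and case count.
#' @export
fit_paths <- function(input, min_n = 500L, min_cases = 20L) {
  stopifnot(inherits(input, "mediation_input"))
  n <- nrow(input)
  cases <- sum(input$y)
  if (n < min_n) stop("mediation sample too small: n = ", n)
  if (cases < min_cases) stop("too few outcome cases: ", cases)
  if (cases == n) stop("outcome is all 1")
  eff <- .fit_paths_core(input$g, input$m1, input$m2, input$y)
  prop_mediated <- if (eff$total != 0) 100 * eff$indirect / eff$total
                   else NA_real_
  prop_iq <- if (eff$indirect != 0) 100 * eff$ind_iq / eff$indirect
             else NA_real_
  prop_res <- if (eff$indirect != 0) 100 * eff$ind_res / eff$indirect
              else NA_real_
  structure(c(eff, list(prop_mediated = prop_mediated, prop_iq = prop_iq,
                        prop_res = prop_res, n = n, cases = cases,
                        disorder = attr(input, "disorder"))),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("<mediation_fit>", if (!is.null(x$disorder)) x$disorder, "n =", x$n,
      "cases =", x$cases, "\n")
  cat(sprintf("  total %+.4f = direct %+.4f + indirect %+.4f (IQ %+.4f, resilience %+.4f)\n",
              x$total, x$direct, x$indirect, x$ind_iq, x$ind_res))
  cat(sprintf("  proportion mediated %.1f%% (via IQ %.1f%%, via resilience %.1f%%)\n",
              x$prop_mediated, x$prop_iq, x$prop_res))
  invisible(x)
}

#' Mediation proportion arithmetic
#'
#' The reporting formulas used for mediation tables: total proportion
#' mediated = indirect / total, via-IQ = (indirect via IQ) / indirect and
#' via-resilience = (indirect via resilience) / indirect, each times 100.
#' Percentages are computed from unrounded effects and rounded only here.
#'
#' @param total,indirect,ind_iq,ind_res Effect estimates. The indirect
#'   effect is taken as given (in an exact decomposition it equals
#'   ind_iq + ind_res and total - direct; reported tables may carry
#'   rounding).
#' @param digits Decimals for the percentages (default 1).
#' @return Named list: prop_mediated, prop_iq, prop_res (percent).
#' @export
mediation_proportions <- function(total, indirect, ind_iq, ind_res,
                                  digits = 1L) {
  list(prop_mediated = round(100 * indirect / total, digits),
       prop_iq = round(100 * ind_iq / indirect, digits),
       prop_res = round(100 * ind_res / indirect, digits))
}

#' Mediation summary table across disorders
#'
#' One row per disorder with the five effects and the three proportion
#' statistics (percentages to one decimal; computed from unrounded
#' effects). When the indirect effect is zero the sub-proportions are
#' reported blank with a note.
#'
#' @param decompositions Named list of [fit_paths()] results (names =
#'   disorder codes), or unnamed if each carries its disorder.
#' @return data.table in report layout.
#' @export
proportion_table <- function(decompositions) {
  rows <- lapply(seq_along(decompositions), function(i) {
    d <- decompositions[[i]]
    stopifnot(inherits(d, "mediation_fit"))
    code <- names(decompositions)[i] %||% d$disorder
    note <- ""
    if (d$indirect == 0) note <- "indirect effect 0; sub-proportions undefined"
    data.table(disorder = code,
               total = round(d$total, 3), direct = round(d$direct, 3),
               indirect = round(d$indirect, 3),
               ind_iq = round(d$ind_iq, 3), ind_res = round(d$ind_res, 3),
               prop_mediated = round(d$prop_mediated, 1),
               prop_iq = round(d$prop_iq, 1),
               prop_res = round(d$prop_res, 1),
               note = note)
  })
  rbindlist(rows)
}

#' Bootstrap test: mediation via IQ versus via resilience
#'
#' Percentile bootstrap over subjects of the difference
#' `delta = a1 b1 - a2 b2` between the IQ- and resilience-mediated
#' effects; two-sided p-value from the sign proportion of the bootstrap
#' distribution.
#'
#' @param input A [mediation_input()].
#' @param n_boot Bootstrap replicates (default 1000; at least 100).
#' @param seed Seed (resampling is fully reproducible).
#' @return List: p_value, delta (point estimate), n_boot_ok.
#' @export
iq_vs_resilience_test <- function(input, n_boot = 1000L, seed = 1L) {
  stopifnot(inherits(input, "mediation_input"))
  if (n_boot < 100L) stop("n_boot must be at least 100")
  point <- .fit_paths_core(input$g, input$m1, input$m2, input$y)
  delta <- point$ind_iq - point$ind_res
  set.seed(stage_seed(seed, "medboot"))
  n <- nrow(input)
  g <- input$g; m1 <- input$m1; m2 <- input$m2; y <- input$y
  deltas <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    eff <- tryCatch(.fit_paths_core(g[idx], m1[idx], m2[idx], y[idx]),
                    error = function(e) NULL)
    if (!is.null(eff)) deltas[b] <- eff$ind_iq - eff$ind_res
  }
  ok <- deltas[!is.na(deltas)]
  if (length(ok) < 100L) stop("too few successful bootstrap replicates")
  p <- 2 * min(mean(ok <= 0), mean(ok >= 0))
  list(p_value = min(p, 1), delta = delta, n_boot_ok = length(ok))
}
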