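## Aalen additive-hazards model with an FGRS x GAEA interaction.
##
## Hazard: lambda(t | x) = b0(t) + sum_j b_j(t) x_j on the time scale of
## months since age 17.  Estimation uses the classical least-squares
## increments: at each event time t_k the cumulative coefficient jump is
## dB(t_k) = (Xk' Xk)^-1 Xk' e_k with Xk the risk-set design matrix and e_k
## the indicator of the (possibly tied) events at t_k.  Risk summaries are
## reported as the %-unit increase in cases over 34 years (408 months), the
## cohort's mean follow-up.

#' Build a survival design for one disorder
#'
#' Follow-up runs from age 17 (time 0) to first registration for the
#' disorder, death, emigration or the administrative end of follow-up.
#' Covariate sets: model A1 = intercept, birth year (centered), sex, FGRS;
#' A2 = intercept, yob, sex, GAEA; B = A1 + GAEA; C = B + FGRS x GAEA
#' (interaction of the standardized scores). Subjects censored at or before
#' entry, or with a missing score, are dropped and counted.
#'
#' @param bundle A `registry_bundle`.
#' @param scores Long score table (id, trait, z) containing the disorder
#'   FGRS and `"GAEA"` as needed, e.g. from [compute_all_scores()].
#' @param disorder Disorder code.
#' @param model One of `"A1"`, `"A2"`, `"B"`, `"C"`.
#' @param sex_filter Optional `"F"` or `"M"`; the sex column is dropped
#'   within a single-sex design.
#' @param probands Optional subject ids (default: all ids scored for the
#'   needed traits).
#' @return A `survival_design`: list(time, status, X, id, dropped).
#' @export
build_design <- function(bundle, scores, disorder,
                         model = c("C", "A1", "A2", "B"),
                         sex_filter = NULL, probands = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(bundle, "registry_bundle"))
  sc <- as.data.table(scores)
  need_fgrs <- model %in% c("A1", "B", "C")
  need_gaea <- model %in% c("A2", "B", "C")

  persons <- bundle$persons
  if (is.null(probands)) probands <- sort(unique(sc$id))
  subj <- persons[id %in% probands,
                  .(id, sex, yob, death_month, emig_month)]
  if (!is.null(sex_filter)) subj <- subj[sex == sex_filter]
  subj[, censor := censor_month(.SD, bundle$meta$admin_end_year %||% 2018L)]

  ev <- bundle$events[disorder, on = "disorder",
                      .(id, ev_age = age_months), nomatch = NULL]
  subj[, ev_age := NA_integer_]
  if (nrow(ev)) subj[ev, ev_age := i.ev_age, on = "id"]
  subj[, status := as.integer(!is.na(ev_age) & ev_age <= censor)]
  subj[, exit := ifelse(status == 1L, ev_age, censor) -
         FOLLOWUP_START_MONTHS]

  n0 <- nrow(subj)
  subj <- subj[exit > 0]
  dropped_entry <- n0 - nrow(subj)

  if (need_fgrs) {
    f <- sc[trait == disorder, .(id, FGRS = z)]
    subj <- merge(subj, f, by = "id", all.x = TRUE)
  }
  if (need_gaea) {
    g <- sc[trait == "GAEA", .(id, GAEA = z)]
    subj <- merge(subj, g, by = "id", all.x = TRUE)
  }
  score_cols <- c(if (need_fgrs) "FGRS", if (need_gaea) "GAEA")
  n1 <- nrow(subj)
  subj <- subj[complete.cases(subj[, score_cols, with = FALSE])]
  dropped_score <- n1 - nrow(subj)
  if (dropped_entry + dropped_score > 0)
    message("build_design(", disorder, ", ", model, "): dropped ",
            dropped_entry, " subject(s) censored at entry and ",
            dropped_score, " with missing scores")
  if (nrow(subj) == 0L) stop("no subjects remain in the design")

  X <- cbind(`(Intercept)` = 1, yob_c = subj$yob - mean(subj$yob))
  if (is.null(sex_filter)) X <- cbind(X, sexF = as.numeric(subj$sex == "F"))
  if (need_fgrs) X <- cbind(X, FGRS = subj$FGRS)
  if (need_gaea) X <- cbind(X, GAEA = subj$GAEA)
  if (model == "C") X <- cbind(X, `FGRS:GAEA` = subj$FGRS * subj$GAEA)

  structure(list(time = as.numeric(subj$exit), status = subj$status,
                 X = X, id = subj$id, model = model, disorder = disorder,
                 dropped = c(at_entry = dropped_entry,
                             missing_score = dropped_score)),
            class = "survival_design")
}

## Core least-squares increment estimator.  Risk-set cross-product matrices
## are accumulated by cumulative sums over subjects ordered by decreasing
## exit time, so each distinct event time costs one p x p solve.
.aalen_core <- function(time, status, X) {
  n <- length(time)
  p <- ncol(X)
  ev_times <- sort(unique(time[status == 1L]))
  m <- length(ev_times)
  if (m == 0L) stop("no events in the design")

  ord <- order(time, decreasing = TRUE)
  Xo <- X[ord, , drop = FALSE]
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  CP <- Xo[, pairs[, 1L], drop = FALSE] * Xo[, pairs[, 2L], drop = FALSE]
  CPcum <- apply(CP, 2L, cumsum)
  if (n == 1L) CPcum <- matrix(CPcum, nrow = 1L)

  sorted_exit <- sort(time)
  n_risk <- n - findInterval(ev_times, sorted_exit, left.open = TRUE)

  ## per-event-time sums of event covariate rows
  evi <- which(status == 1L)
  grp <- match(time[evi], ev_times)
  Xe <- rowsum(X[evi, , drop = FALSE], grp, reorder = TRUE)
  n_event <- as.vector(rowsum(rep(1L, length(evi)), grp, reorder = TRUE))

  dB <- matrix(0, m, p, dimnames = list(NULL, colnames(X)))
  skipped <- logical(m)
  M <- matrix(0, p, p)
  iu <- cbind(pairs[, 1L], pairs[, 2L])
  il <- cbind(pairs[, 2L], pairs[, 1L])
  for (k in seq_len(m)) {
    v <- CPcum[n_risk[k], ]
    M[iu] <- v
    M[il] <- v
    inc <- tryCatch(solve(M, Xe[k, ]), error = function(e) NULL)
    if (is.null(inc)) skipped[k] <- TRUE else dB[k, ] <- inc
  }
  if (all(skipped))
    stop("risk-set design rank-deficient at every event time")
  B <- apply(dB, 2L, cumsum)
  if (m == 1L) B <- matrix(B, 1L, p, dimnames = list(NULL, colnames(X)))
  list(times = ev_times, dB = dB, B = B, n_risk = n_risk,
       n_event = n_event, skipped = skipped)
}

#' Fit an Aalen additive-hazards model
#'
#' @param design A [build_design()] result (or any list with numeric
#'   `time`, 0/1 `status` and matrix `X`).
#' @return An `aalen_fit`: event times, coefficient increments `dB`,
#'   cumulative coefficients `B` (piecewise constant, jumping only at event
#'   times, `B(0) = 0`), numbers at risk and of (tied, jointly processed)
#'   events, and a flag for increments skipped due to rank deficiency.
#' @export
fit_aalen <- function(design) {
  stopifnot(!is.null(design$time), !is.null(design$status),
            is.matrix(design$X))
  core <- .aalen_core(design$time, design$status, design$X)
  if (any(core$skipped))
    message("fit_aalen: skipped ", sum(core$skipped),
            " rank-deficient increment(s)")
  structure(c(core,
              list(terms = colnames(design$X),
                   n = length(design$time),
                   xbar = colMeans(design$X),
                   design = design)),
            class = "aalen_fit")
}

#' @export
print.aalen_fit <- function(x, ...) {
  cat("<aalen_fit> ", x$n, " subjects, ", sum(x$n_event), " events at ",
      length(x$times), " distinct times; terms: ",
      paste(x$terms, collapse = ", "), "\n", sep = "")
  invisible(x)
}

## Cumulative coefficients at the last event time <= t_star.
.B_at <- function(fit, t_star) {
  idx <- max(which(fit$times <= t_star), -Inf)
  if (!is.finite(idx)) stop("no event before ", t_star, " months")
  fit$B[idx, ]
}

#' Summarize a fit as the %-unit increase in cases per 34 years
#'
#' Reports `100 * B_j(T*)` with `T* = 408` months (34 years, the cohort
#' mean follow-up), i.e. the percentage-unit increase in 34-year cases per
#' unit of each covariate, evaluated at the last event time at or before
#' `T*`. Confidence intervals by seeded nonparametric bootstrap over
#' subjects.
#'
#' @param fit An [fit_aalen()] result.
#' @param t_star Horizon in months (default 408).
#' @param n_boot Bootstrap replicates (default 200; 0 skips the CI).
#' @param seed Seed for the bootstrap resampling.
#' @param level Confidence level (default 0.95).
#' @return A `risk_summary` data.table (term, estimate, ci_low, ci_high).
#' @export
summarize_34y <- function(fit, t_star = T_STAR_MONTHS, n_boot = 200L,
                          seed = 1L, level = 0.95) {
  stopifnot(inherits(fit, "aalen_fit"))
  est <- 100 * .B_at(fit, t_star)
  lo <- hi <- rep(NA_real_, length(est))
  if (n_boot > 0L) {
    d <- fit$design
    if (is.null(d$time)) stop("fit carries no subject data to bootstrap")
    set.seed(stage_seed(seed, "boot34"))
    n <- length(d$time)
    bs <- matrix(NA_real_, n_boot, length(est))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      core <- tryCatch(
        .aalen_core(d$time[idx], d$status[idx], d$X[idx, , drop = FALSE]),
        error = function(e) NULL)
      if (is.null(core)) next
      bidx <- max(which(core$times <= t_star), -Inf)
      if (is.finite(bidx)) bs[b, ] <- 100 * core$B[bidx, ]
    }
    a <- (1 - level) / 2
    qs <- apply(bs, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE)
    lo <- qs[1L, ]
    hi <- qs[2L, ]
  }
  out <- data.table(term = fit$terms, estimate = est,
                    ci_low = lo, ci_high = hi)
  setattr(out, "class", c("risk_summary", class(out)))
  out[]
}

#' Predicted 34-year rates over an FGRS grid at fixed GAEA levels
#'
#' Evaluates the linear predictor `x' B(T*)` of a fitted interaction model
#' over a grid of FGRS values at GAEA levels -2..+2 SD, with the remaining
#' covariates (sex, birth year) at their sample means. Predicted rates are
#' clamped to `[0, 1]` (linear hazards can stray outside); clamping is
#' reported.
#'
#' @param fit An [fit_aalen()] result whose terms include `FGRS` and
#'   `GAEA` (model C also has `FGRS:GAEA`).
#' @param fgrs_grid FGRS values (default -3..3 by 0.25).
#' @param gaea_levels GAEA values (default -2, -1, 0, 1, 2).
#' @param t_star Horizon in months (default 408).
#' @return data.table(gaea, fgrs, rate).
#' @export
prediction_grid <- function(fit, fgrs_grid = seq(-3, 3, by = 0.25),
                            gaea_levels = c(-2, -1, 0, 1, 2),
                            t_star = T_STAR_MONTHS) {
  stopifnot(inherits(fit, "aalen_fit"))
  if (!all(c("FGRS", "GAEA") %in% fit$terms))
    stop("prediction_grid needs a fit with FGRS and GAEA terms (model C)")
  B <- .B_at(fit, t_star)
  grid <- CJ(gaea = gaea_levels, fgrs = fgrs_grid)
  xref <- fit$xbar
  rate <- vapply(seq_len(nrow(grid)), function(i) {
    x <- xref
    x["FGRS"] <- grid$fgrs[i]
    x["GAEA"] <- grid$gaea[i]
    if ("FGRS:GAEA" %in% names(x))
      x["FGRS:GAEA"] <- grid$fgrs[i] * grid$gaea[i]
    sum(x * B)
  }, 0)
  n_clamped <- sum(rate < 0 | rate > 1)
  if (n_clamped > 0)
    message("prediction_grid: clamped ", n_clamped,
            " predicted rate(s) to [0, 1]")
  grid[, rate := pmin(pmax(rate, 0), 1)]
  grid[]
}
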