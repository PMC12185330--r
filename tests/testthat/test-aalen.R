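## Independent Nelson-Aalen estimator (cumulative hazard at event times).
nelson_aalen <- function(time, status) {
  ut <- sort(unique(time[status == 1]))
  H <- numeric(length(ut))
  acc <- 0
  for (k in seq_along(ut)) {
    d <- sum(time == ut[k] & status == 1)
    r <- sum(time >= ut[k])
    acc <- acc + d / r
    H[k] <- acc
  }
  list(times = ut, H = H)
}

test_that("design matrices have the model-specific column sets", {
  b <- small_bundle()
  pr <- cohort_ids(b)
  lk <- relative_links(pedigree_graph(b$pedigree), pr, cohab = b$cohab)
  sc <- suppressWarnings(
    compute_all_scores(b, lk, probands = pr, traits = c("MD", "GAEA")))
  dC <- suppressMessages(build_design(b, sc, "MD", model = "C"))
  expect_equal(colnames(dC$X),
               c("(Intercept)", "yob_c", "sexF", "FGRS", "GAEA",
                 "FGRS:GAEA"))
  dA1 <- suppressMessages(build_design(b, sc, "MD", model = "A1"))
  expect_equal(colnames(dA1$X), c("(Intercept)", "yob_c", "sexF", "FGRS"))
  dA2 <- suppressMessages(build_design(b, sc, "MD", model = "A2"))
  expect_equal(colnames(dA2$X), c("(Intercept)", "yob_c", "sexF", "GAEA"))
  dB <- suppressMessages(build_design(b, sc, "MD", model = "B",
                                      sex_filter = "F"))
  expect_equal(colnames(dB$X), c("(Intercept)", "yob_c", "FGRS", "GAEA"))
  ## all subjects enter at age 17 and exit strictly later
  expect_true(all(dC$time > 0))
  ## zero scores give a zero interaction column
  i0 <- which(dC$X[, "FGRS"] == 0 | dC$X[, "GAEA"] == 0)
  expect_true(all(dC$X[i0, "FGRS:GAEA"] == 0))
})

test_that("subjects censored at entry are excluded and counted", {
  b <- small_bundle()
  pr <- cohort_ids(b)
  lk <- relative_links(pedigree_graph(b$pedigree), pr, cohab = b$cohab)
  sc <- suppressWarnings(
    compute_all_scores(b, lk, probands = pr, traits = c("MD", "GAEA")))
  ## force one subject to die in childhood
  b2 <- b
  b2$persons <- copy(b$persons)
  victim <- setdiff(pr, b$events$id)[1]
  b2$persons[id == victim, death_month := 100L]
  b2$events <- b$events[id != victim]
  expect_message(build_design(b2, sc, "MD", model = "C"),
                 "censored at entry")
  d <- suppressMessages(build_design(b2, sc, "MD", model = "C"))
  expect_false(victim %in% d$id)
  expect_gte(d$dropped[["at_entry"]], 1)
})

test_that("the covariate-free fit is exactly Nelson-Aalen", {
  set.seed(41)
  n <- 500
  tt <- rexp(n, 0.02)
  cens <- runif(n, 5, 100)
  time <- pmin(tt, cens)
  status <- as.integer(tt <= cens)
  fit <- fit_aalen(list(time = time, status = status,
                        X = matrix(1, n, 1,
                                   dimnames = list(NULL, "(Intercept)"))))
  na <- nelson_aalen(time, status)
  expect_equal(fit$times, na$times)
  expect_equal(unname(fit$B[, 1]), na$H, tolerance = 1e-12)
})

test_that("a binary covariate reduces to group-wise Nelson-Aalen", {
  set.seed(42)
  n <- 600
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.01 + 0.01 * x)  # no censoring
  status <- rep(1L, n)
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_aalen(list(time = time, status = status, X = X))
  na0 <- nelson_aalen(time[x == 0], status[x == 0])
  na1 <- nelson_aalen(time[x == 1], status[x == 1])
  ## the group decomposition holds while both groups are at risk; once one
  ## group's risk set empties the design is rank-deficient and increments
  ## are skipped (by design), so compare on the common support
  both <- min(max(time[x == 1]), max(time[x == 0]))
  B0 <- stats::stepfun(fit$times, c(0, fit$B[, 1]))
  B01 <- stats::stepfun(fit$times, c(0, fit$B[, 1] + fit$B[, 2]))
  t0g <- na0$times[na0$times <= both]
  t1g <- na1$times[na1$times <= both]
  expect_gt(length(t0g), 100)
  expect_lt(max(abs(B0(t0g) - na0$H[na0$times <= both])), 1e-8)
  expect_lt(max(abs(B01(t1g) - na1$H[na1$times <= both])), 1e-8)
})

test_that("the estimator agrees with survival::aareg on seeded data", {
  skip_if_not_installed("survival")
  for (s in 1:3) {
    set.seed(400 + s)
    n <- 300
    x1 <- rbinom(n, 1, 0.4)
    x2 <- rnorm(n)
    haz <- pmax(0.02 + 0.01 * x1 + 0.004 * x2, 1e-4)
    tt <- rexp(n, haz)
    cens <- runif(n, 10, 90)
    time <- pmin(tt, cens)
    status <- as.integer(tt <= cens)
    fit <- fit_aalen(list(time = time, status = status,
                          X = cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)))
    ar <- survival::aareg(survival::Surv(time, status) ~ x1 + x2)
    expect_equal(nrow(ar$coefficient), length(fit$times))
    expect_lt(max(abs(fit$dB - ar$coefficient)), 1e-8)
  }
})

test_that("a planted additive hazard is recovered at n = 20,000", {
  set.seed(43)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  X <- cbind(`(Intercept)` = 1, x = x)
  d <- sim_additive_survival(n, c(0.001, 0.0005), X, cens_months = 500)
  fit <- fit_aalen(d)
  slope <- 100 * gaeamod:::.B_at(fit, 408)[["x"]] / 408
  expect_lt(abs(slope - 0.05), 0.15 * 0.05)
})

test_that("34-year summaries: plateau, linear scaling, CI coverage", {
  set.seed(44)
  n <- 2000
  x <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, x = x)
  d <- sim_additive_survival(n, c(0.004, 0), X, cens_months = 100)
  des <- list(time = d$time, status = d$status, X = d$X)
  fit <- fit_aalen(des)
  ## all events at or before month 100: summary equals B at the last event
  sm <- summarize_34y(fit, n_boot = 0)
  expect_equal(sm$estimate,
               unname(100 * fit$B[nrow(fit$B), ]))
  ## doubling a covariate column halves its cumulative coefficient
  X2 <- X; X2[, "x"] <- 2 * X2[, "x"]
  fit2 <- fit_aalen(list(time = d$time, status = d$status, X = X2))
  sm2 <- summarize_34y(fit2, n_boot = 0)
  expect_equal(sm2$estimate[2], sm$estimate[2] / 2, tolerance = 1e-8)
  ## bootstrap CI of a null covariate covers 0 most of the time
  cover <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    set.seed(4400 + r)
    xs <- rnorm(400)
    Xs <- cbind(`(Intercept)` = 1, x = xs)
    ds <- sim_additive_survival(400, c(0.004, 0), Xs, cens_months = 450)
    fs <- fit_aalen(list(time = ds$time, status = ds$status, X = ds$X))
    ss <- summarize_34y(fs, n_boot = 100, seed = r)
    if (ss$ci_low[2] <= 0 && ss$ci_high[2] >= 0) cover <- cover + 1
  }
  expect_gte(cover, 0.9 * n_rep)
})

test_that("a planted negative interaction is detected in >= 45/50 runs", {
  hits <- 0
  for (s in 1:50) {
    set.seed(500 + s)
    n <- 8000
    f <- rnorm(n)
    g <- -0.3 * f + sqrt(1 - 0.09) * rnorm(n)
    X <- cbind(`(Intercept)` = 1, FGRS = f, GAEA = g, `FGRS:GAEA` = f * g)
    beta <- c(0.004, 0.001, -0.0005, -0.0006)
    d <- sim_additive_survival(n, beta, X, cens_months = 408)
    fit <- fit_aalen(d)
    sm <- summarize_34y(fit, n_boot = 0)
    if (sm$estimate[sm$term == "FGRS:GAEA"] < 0) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("prediction grids: flat when null, fan-shaped under a negative
           interaction, clamped at zero", {
  set.seed(45)
  n <- 5000
  f <- rnorm(n); g <- rnorm(n)
  X <- cbind(`(Intercept)` = 1, FGRS = f, GAEA = g, `FGRS:GAEA` = f * g)
  d0 <- sim_additive_survival(n, c(0.0008, 0.0002, -0.0001, -0.00012), X,
                              cens_months = 500)
  fit <- fit_aalen(d0)
  ## with every coefficient zeroed except the intercept the grid is flat
  fit_flat <- fit
  fit_flat$B[] <- 0
  fit_flat$B[, 1] <- 0.3
  fit_flat$xbar[] <- c(1, 0, 0, 0)
  g0 <- prediction_grid(fit_flat)
  expect_true(all(g0$rate == 0.3))
  ## a linear predictor below zero clamps to zero
  fit_neg <- fit_flat
  fit_neg$B[, 1] <- 0.001
  fit_neg$B[, 2] <- 0.1   # FGRS coefficient
  expect_message(gneg <- prediction_grid(fit_neg), "clamped")
  expect_equal(gneg[fgrs == -3 & gaea == 0, rate], 0)
  ## planted negative interaction: gaea-level spread grows with FGRS
  g1 <- suppressMessages(prediction_grid(fit))
  spread <- g1[, .(s = max(rate) - min(rate)), by = fgrs]
  expect_gt(spread[fgrs == 3, s], spread[fgrs == -3, s])
  expect_true(all(g1$rate >= 0 & g1$rate <= 1))
})

test_that("degenerate designs raise the documented errors", {
  X <- matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)"))
  expect_error(fit_aalen(list(time = 1:10, status = rep(0L, 10), X = X)),
               "no events")
  fit <- fit_aalen(list(time = c(500, 600, 1:8), status = rep(1L, 10),
                        X = X))
  expect_error(summarize_34y(fit, t_star = 0.5, n_boot = 0),
               "no event before")
})
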