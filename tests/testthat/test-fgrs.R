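## Quadrature oracle for the truncated-normal mean liability of an
## affected relative: E[X | X > tau] with X standard normal.
quad_affected_mean <- function(K) {
  tau <- qnorm(1 - K)
  integrate(function(x) x * dnorm(x), tau, Inf,
            rel.tol = 1e-12)$value / K
}

test_that("liability contributions match truncated-normal means", {
  m <- liability_model(0.5)
  expect_equal(relative_contribution(m, TRUE), dnorm(0) / 0.5,
               tolerance = 1e-10)
  for (K in c(0.002, 0.005, 0.013, 0.05, 0.2)) {
    m <- liability_model(K)
    expect_lt(abs(m$z_affected - quad_affected_mean(K)), 1e-6)
    ## mean-zero identity: K * z+ + (1 - K) * z- = 0
    expect_lt(abs(K * m$z_affected + (1 - K) * m$z_unaffected), 1e-10)
  }
  expect_error(liability_model(0), "in \\(0, 1\\)")
  expect_error(liability_model(1.2), "in \\(0, 1\\)")
})

test_that("a single affected parent gives the hand-computed raw score", {
  persons <- data.table(id = 1:2, sex = c("M", "M"),
                        yob = c(1980L, 1955L), county = "C1",
                        death_month = NA_integer_, emig_month = NA_integer_,
                        ea_z = 0, iq_z = NA_real_, res_z = NA_real_)
  ped <- data.table(id = 1:2, father_id = c(2L, NA), mother_id = NA_integer_)
  ev <- data.table(id = 2L, disorder = "MD", age_months = 300L)
  b <- make_bundle(persons, ped, ev)
  links <- data.table(proband = 1L, relative = 2L, phi = 0.25,
                      relatedness = 0.5, degree = 1L, cohab_years = 15)
  sc <- suppressWarnings(
    compute_fgrs(b, links, "MD", model = liability_model(0.05),
                 config = scoring_config(lambda = 0, cohab_adjust = FALSE),
                 probands = 1L))
  expect_equal(sc$raw, dnorm(qnorm(0.95)) / 0.05, tolerance = 1e-6)
  expect_equal(sc$raw, 2.0627, tolerance = 1e-4)
  expect_equal(sc$weight_sum, 0.5)
})

test_that("probands without phenotyped relatives score raw zero", {
  b <- small_bundle()
  pr <- cohort_ids(b)[1:50]
  links <- data.table(proband = integer(), relative = integer(),
                      phi = numeric(), relatedness = numeric(),
                      degree = integer(), cohab_years = numeric())
  sc <- suppressWarnings(compute_fgrs(b, links, "MD", probands = pr))
  expect_true(all(sc$raw == 0))
  expect_true(all(sc$weight_sum == 0))
})

test_that("standardized scores have mean 0 and SD 1 within every stratum", {
  ms <- medium_scores()
  sc <- ms$scores[trait == "DUD"]
  info <- ms$bundle$persons[, .(id, yob, county)]
  m <- merge(sc, info, by = "id")
  st <- m[, .(mu = mean(z), sdv = sd(z), n = .N), by = .(yob, county)]
  st <- st[n >= 2 & sdv > 0]
  expect_true(all(abs(st$mu) < 1e-8))
  expect_true(all(abs(st$sdv - 1) < 1e-8))
})

test_that("cohabitation adjustment is a pass-through for constant years", {
  set.seed(21)
  z <- rnorm(50)
  expect_equal(cohabitation_adjust(z, rep(1L, 50), rep(15, 50)), z)
  ## too-small class: pass-through
  expect_equal(cohabitation_adjust(z[1:5], rep(2L, 5), rnorm(5)), z[1:5])
})

test_that("cohabitation adjustment recovers a planted slope and leaves
           independent contributions nearly unchanged", {
  set.seed(22)
  nI <- 4000
  xI <- pmax(0, rnorm(nI, 10, 4))
  z_ind <- rnorm(nI)
  adj <- cohabitation_adjust(z_ind, rep(1L, nI), xI)
  expect_lt(mean(abs(adj - z_ind)), 0.05)
  n <- 1000
  x <- pmax(0, rnorm(n, 10, 4))
  z_dep <- 0.1 * x + rnorm(n)
  adj2 <- cohabitation_adjust(z_dep, rep(1L, n), x)
  slope_removed <- coef(lm(I(z_dep - adj2) ~ x))[2]
  expect_lt(abs(slope_removed - 0.1), 0.02)
  ## class mean preserved
  expect_equal(mean(adj2), mean(z_dep), tolerance = 1e-10)
})

test_that("adding an affected first-degree relative never lowers the FGRS", {
  set.seed(23)
  m <- liability_model(0.05)
  for (rep in 1:20) {
    k <- sample(1:6, 1)
    w <- 2 * sample(c(0.25, 0.125, 0.0625), k, replace = TRUE)
    zc <- relative_contribution(m, runif(k) < 0.3)
    lambda <- runif(1, 0, 3)
    raw0 <- sum(w * zc) / (sum(w) + lambda)
    raw1 <- (sum(w * zc) + 0.5 * m$z_affected) /
      (sum(w) + 0.5 + lambda)
    expect_gte(raw1, raw0)
  }
})

test_that("FGRS recovers true genetic liability, more so with more relatives", {
  ms <- medium_scores()
  sc <- merge(ms$scores[trait == "DUD"], ms$bundle$truth[, .(id, g_DUD)],
              by = "id")
  nrel <- ms$links[, .N, by = proband]
  sc[nrel, n_rel := i.N, on = c(id = "proband")]
  sc[is.na(n_rel), n_rel := 0L]
  r_all <- cor(sc$z, sc$g_DUD)
  expect_gt(r_all, 0.15)
  med <- median(sc$n_rel)
  r_few <- sc[n_rel < med, cor(z, g_DUD)]
  r_many <- sc[n_rel >= med, cor(z, g_DUD)]
  expect_gt(r_many, r_few)
})

test_that("negative EA-DUD genetic correlation shows in the scores", {
  ms <- medium_scores()
  est <- score_correlation(ms$scores[trait == "DUD"],
                           ms$scores[trait == "GAEA"])
  expect_lt(est$rho, 0)
})
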