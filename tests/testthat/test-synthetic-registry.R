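test_that("the same seed reproduces the bundle exactly; seeds differ", {
  cfg <- sim_config(n_founder_couples = 30L, seed = 1L)
  b1 <- simulate_population(cfg)
  b2 <- simulate_population(cfg)
  expect_identical(b1$persons, b2$persons)
  expect_identical(b1$pedigree, b2$pedigree)
  expect_identical(b1$events, b2$events)
  expect_identical(b1$cohab, b2$cohab)
  b3 <- simulate_population(sim_config(n_founder_couples = 30L, seed = 2L))
  expect_false(identical(b1$persons, b3$persons))
})

test_that("zero heritability decouples offspring from parental liability", {
  specs <- default_disorder_specs()
  for (s in names(specs)) specs[[s]]$heritability <- 0
  cfg <- sim_config(n_founder_couples = 1200L, disorder_specs = specs,
                    gaea_spec = list(h2_ea = 0, r_g = default_rg_ea()),
                    seed = 3L)
  b <- simulate_population(cfg)
  ped <- b$pedigree[!is.na(father_id)]
  tr <- b$truth
  kid <- merge(ped, tr[, .(id, liab_MD)], by = "id")
  kid <- merge(kid, tr[, .(father_id = id, liab_f = liab_MD)],
               by = "father_id")
  expect_gt(nrow(kid), 10000)
  expect_lt(abs(cor(kid$liab_MD, kid$liab_f)), 0.05)
})

test_that("rare-disorder prevalence matches the configured K (binomial)", {
  b <- medium_bundle()
  pr <- cohort_ids(b)
  expect_gt(length(pr), 50000)
  prev <- prevalence_summary(b, ids = pr)
  obs <- prev[disorder == "SZ", prevalence_pct] / 100
  K <- 0.002
  band <- 3 * sqrt(K * (1 - K) / length(pr))
  expect_lt(abs(obs - K), band + 0.0002)  # small deficit from pre-17 censoring
})

test_that("sibling liability correlation is about h2/2", {
  b <- medium_bundle()
  kids <- b$pedigree[!is.na(father_id) & !is.na(mother_id)]
  sib <- kids[kids, on = c("father_id", "mother_id"),
              allow.cartesian = TRUE][id < i.id, .(a = id, b = i.id)]
  expect_gt(nrow(sib), 20000)
  tr <- b$truth
  for (d in c("MD", "ADHD")) {
    lv <- setNames(tr[[paste0("liab_", d)]], tr$id)
    r <- cor(lv[as.character(sib$a)], lv[as.character(sib$b)])
    h2 <- default_disorder_specs()[[d]]$heritability
    expect_lt(abs(r - h2 / 2), 0.03)
  }
})

test_that("EA-genetic vs disorder-liability correlation matches r_g", {
  b <- medium_bundle()
  tr <- b$truth
  expect_gt(nrow(tr), 50000)
  rg <- default_rg_ea()
  for (d in c("DUD", "AD", "BN")) {
    ## genetic-value correlation equals the configured r_g
    expect_lt(abs(cor(tr$g_EA, tr[[paste0("g_", d)]]) - rg[d]), 0.03)
    ## on the liability scale it attenuates by sqrt(h2)
    h2 <- default_disorder_specs()[[d]]$heritability
    expect_lt(abs(cor(tr$g_EA, tr[[paste0("liab_", d)]]) -
                    rg[d] * sqrt(h2)), 0.03)
  }
})

test_that("no event follows censoring and all events are within follow-up", {
  b <- small_bundle()
  expect_true(validate_bundle(b))
  cm <- setNames(gaeamod:::censor_month(b$persons), b$persons$id)
  expect_true(all(b$events$age_months <= cm[as.character(b$events$id)]))
  expect_true(all(b$events$age_months >= 204))
  expect_equal(anyDuplicated(b$events[, .(id, disorder)]), 0L)
})

test_that("a non-PSD genetic correlation matrix is rejected by name", {
  rg <- default_rg_ea()
  rg["DUD"] <- -0.99
  rg["AUD"] <- -0.99
  rg["ADHD"] <- -0.99
  expect_error(sim_config(gaea_spec = list(h2_ea = 0.4, r_g = rg)),
               "positive semi-definite.*DUD|positive semi-definite.*AUD")
})

test_that("bundle round-trips through CSV", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  b2 <- read_bundle(dir, cohort_range = b$meta$cohort_range)
  for (part in c("persons", "pedigree", "events", "cohab"))
    expect_equal(as.data.frame(b2[[part]]), as.data.frame(b[[part]]),
                 tolerance = 1e-12)
})

test_that("an event-free bundle reads back as a valid zero-case registry", {
  b <- small_bundle()
  b0 <- make_bundle(b$persons, b$pedigree)
  dir <- withr::local_tempdir()
  write_bundle(b0, dir)
  b2 <- read_bundle(dir)
  expect_equal(nrow(b2$events), 0L)
  prev <- prevalence_summary(b2, disorders = "MD")
  expect_equal(prev$prevalence_pct, 0)
})

test_that("a corrupted header raises a schema error naming the columns", {
  b <- small_bundle()
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  ev <- fread(file.path(dir, "events.csv"))
  setnames(ev, "age_months", "age")
  fwrite(ev, file.path(dir, "events.csv"))
  expect_error(read_bundle(dir), "schema mismatch.*age_months")
})
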