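## End-to-end orchestration: simulate -> score -> correlate -> fit ->
## mediate, with optional sex- and cohort-stratified reruns, writing
## registry-study style CSV outputs plus a manifest with content hashes.

#' Configure a pipeline run
#'
#' @param sim A [sim_config()] (used unless `bundle_dir` is given).
#' @param bundle_dir Optional directory with a previously written bundle;
#'   read instead of simulating.
#' @param disorders Disorders to analyse (default all ten).
#' @param models Aalen model set (subset of A1, A2, B, C; at least one).
#' @param sex `"all"`, `"F"` or `"M"`: stratum for the hazard models.
#' @param cohort_split If `TRUE`, rerun the hazard models separately for
#'   the 1973-1983 and 1984-1995 birth cohorts.
#' @param mediation_disorders Disorders for the male mediation analysis
#'   (default the five most prevalent: DUD, AUD, ADHD, MD, AD).
#' @param scoring A [scoring_config()].
#' @param n_boot Bootstrap replicates for hazard-summary CIs (0 = point
#'   estimates only, the default for full-table runs) and for the mediation
#'   IQ-vs-resilience test (floored at 100 there).
#' @param seed Master seed; all stages draw from named substreams of it.
#' @param outdir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), bundle_dir = NULL,
                       disorders = DISORDER_CODES,
                       models = c("A1", "A2", "B", "C"),
                       sex = c("all", "F", "M"),
                       cohort_split = FALSE,
                       mediation_disorders = c("DUD", "AUD", "ADHD",
                                               "MD", "AD"),
                       scoring = scoring_config(),
                       n_boot = 0L,
                       seed = 1L,
                       outdir = tempfile("gaeamod_run_")) {
  sex <- match.arg(sex)
  models <- match.arg(models, c("A1", "A2", "B", "C"), several.ok = TRUE)
  if (length(models) < 1L) stop("at least one model required")
  structure(list(sim = sim, bundle_dir = bundle_dir, disorders = disorders,
                 models = models, sex = sex, cohort_split = cohort_split,
                 mediation_disorders = mediation_disorders,
                 scoring = scoring, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

#' Per-disorder lifetime prevalence
#'
#' Counts persons with at least one registration per disorder (each person
#' once, however many events they have) over the cohort size, in percent.
#'
#' @param bundle A `registry_bundle`.
#' @param ids Optional person ids defining the cohort (default
#'   [cohort_ids()]).
#' @param disorders Disorders to report (default: all with events, in
#'   [DISORDER_CODES] order).
#' @return data.table(disorder, cases, cohort_n, prevalence_pct).
#' @export
prevalence_summary <- function(bundle, ids = NULL, disorders = NULL) {
  stopifnot(inherits(bundle, "registry_bundle"))
  if (is.null(ids)) ids <- cohort_ids(bundle)
  ev <- unique(bundle$events[id %in% ids, .(id, disorder)])
  if (is.null(disorders)) {
    disorders <- intersect(DISORDER_CODES, unique(ev$disorder))
    if (length(disorders) == 0L) disorders <- unique(ev$disorder)
  }
  n <- length(ids)
  counts <- ev[, .N, by = disorder]
  out <- data.table(disorder = disorders)
  out[counts, cases := i.N, on = "disorder"]
  out[is.na(cases), cases := 0L]
  out[, cohort_n := n]
  out[, prevalence_pct := prevalence_pct(cases, n)]
  out[]
}

.log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  invisible(msg)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or read) the bundle; build the pedigree and 1st-5th
#' degree relative links; score all disorder FGRS plus GAEA; produce the
#' prevalence/correlation table (table1.csv), the Aalen model summaries
#' (table2.csv), the male mediation table (table3.csv) and the model-C
#' prediction grids (grids.csv); write manifest.json (config echo, stage
#' row counts, md5 content hashes) and run.log. Deterministic given the
#' config seed.
#'
#' @param config A [run_config()].
#' @return The manifest (list), invisibly; files under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  cat("", file = log_path)
  manifest <- list(config = list(seed = config$seed,
                                 disorders = config$disorders,
                                 models = config$models, sex = config$sex,
                                 cohort_split = config$cohort_split,
                                 n_boot = config$n_boot),
                   stages = list(), outputs = list())
  stage <- function(name, expr) {
    .log_line(log_path, "stage ", name, " start")
    res <- tryCatch(expr, error = function(e) {
      .log_line(log_path, "stage ", name, " FAILED: ", conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$outdir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    .log_line(log_path, "stage ", name, " done")
    res
  }

  ## ---- simulate / load --------------------------------------------------
  bundle <- stage("simulate", {
    if (!is.null(config$bundle_dir)) read_bundle(config$bundle_dir)
    else {
      sim <- config$sim
      sim$seed <- stage_seed(config$seed, "bundle")
      simulate_population(sim)
    }
  })
  probands <- cohort_ids(bundle)
  manifest$stages$simulate <- list(n_persons = nrow(bundle$persons),
                                   n_events = nrow(bundle$events),
                                   n_probands = length(probands))
  .log_line(log_path, "cohort size ", length(probands))

  ## ---- kinship links ----------------------------------------------------
  links <- stage("links", {
    graph <- pedigree_graph(bundle$pedigree)
    relative_links(graph, probands, max_degree = 5L, cohab = bundle$cohab)
  })
  manifest$stages$links <-
    list(n_links = nrow(links),
         mean_relatives = round(nrow(links) / length(probands), 2))

  ## ---- scores -----------------------------------------------------------
  scores <- stage("scores", suppressWarnings(
    compute_all_scores(bundle, links, config = config$scoring,
                       probands = probands,
                       traits = c(config$disorders, "GAEA"))))
  manifest$stages$scores <- list(n_rows = nrow(scores))

  ## ---- table 1: prevalence + correlations -------------------------------
  table1 <- stage("table1", {
    prev <- prevalence_summary(bundle, ids = probands,
                               disorders = config$disorders)
    gaea <- scores[trait == "GAEA"]
    rows <- lapply(config$disorders, function(d) {
      fs <- scores[trait == d]
      pm <- score_correlation(fs, gaea, method = "product-moment")
      tc <- score_correlation(fs, gaea, method = "tetrachoric")
      data.table(disorder = d,
                 corr_pm = round(pm$rho, 3), corr_pm_se = round(pm$se, 4),
                 corr_tetra = round(tc$rho, 3),
                 corr_tetra_se = round(tc$se, 4))
    })
    merge(prev, rbindlist(rows), by = "disorder", sort = FALSE)
  })

  ## ---- table 2: Aalen models (+ strata) ---------------------------------
  sexes <- if (config$sex == "all") list(NULL) else list(config$sex)
  cohorts <- list(c(NA, NA))
  if (config$cohort_split)
    cohorts <- list(c(1973L, 1983L), c(1984L, 1995L))
  fits_C <- list()
  table2 <- stage("table2", {
    rows <- list()
    for (co in cohorts) {
      ids_co <- if (is.na(co[1])) probands
                else intersect(probands, cohort_ids(bundle, co))
      for (sx in sexes) {
        for (d in config$disorders) {
          for (mdl in config$models) {
            row <- tryCatch({
              des <- suppressMessages(
                build_design(bundle, scores, d, model = mdl,
                             sex_filter = sx, probands = ids_co))
              fit <- suppressMessages(fit_aalen(des))
              if (mdl == "C" && is.na(co[1]))
                fits_C[[paste0(d, if (!is.null(sx)) paste0(":", sx))]] <- fit
              sm <- summarize_34y(fit, n_boot = config$n_boot,
                                  seed = config$seed)
              dt <- as.data.table(sm)
              dt[, `:=`(disorder = d, model = mdl,
                        sex = if (is.null(sx)) "all" else sx,
                        cohort = if (is.na(co[1])) "all"
                                 else paste(co, collapse = "-"))]
              dt
            }, error = function(e) {
              .log_line(log_path, "table2 row skipped (", d, ", ", mdl,
                        if (!is.null(sx)) paste0(", sex=", sx), "): ",
                        conditionMessage(e))
              NULL
            })
            if (!is.null(row)) rows[[length(rows) + 1L]] <- row
          }
        }
      }
    }
    if (length(rows) == 0L) stop("no Aalen model could be fitted")
    out <- rbindlist(rows)
    out[, estimate := round(estimate, 4)]
    setcolorder(out, c("disorder", "model", "sex", "cohort", "term",
                       "estimate", "ci_low", "ci_high"))
    out
  })

  ## ---- prediction grids (model C) ---------------------------------------
  grids <- stage("grids", {
    gs <- lapply(names(fits_C), function(nm) {
      g <- suppressMessages(prediction_grid(fits_C[[nm]]))
      g[, disorder := sub(":.*$", "", nm)]
      g
    })
    if (length(gs) == 0L)
      data.table(disorder = character(), gaea = numeric(),
                 fgrs = numeric(), rate = numeric())
    else {
      out <- rbindlist(gs)
      out[, rate := round(rate, 5)]
      setcolorder(out, c("disorder", "gaea", "fgrs", "rate"))
      out
    }
  })

  ## ---- table 3: mediation (males) ---------------------------------------
  table3 <- stage("table3", {
    gaea <- scores[trait == "GAEA"]
    fits <- list()
    pvals <- list()
    for (d in config$mediation_disorders) {
      res <- tryCatch({
        inp <- mediation_input(bundle, gaea, d)
        inp <- inp[id %in% probands]
        setattr(inp, "class", c("mediation_input", "data.table",
                                "data.frame"))
        setattr(inp, "disorder", d)
        f <- fit_paths(inp)
        p <- if (config$n_boot >= 100L)
          iq_vs_resilience_test(inp, n_boot = config$n_boot,
                                seed = config$seed)$p_value
        else NA_real_
        list(fit = f, p = p)
      }, error = function(e) {
        .log_line(log_path, "table3 row skipped (", d, "): ",
                  conditionMessage(e))
        NULL
      })
      if (!is.null(res)) {
        fits[[d]] <- res$fit
        pvals[[d]] <- res$p
      }
    }
    if (length(fits) == 0L)
      data.table(disorder = character())
    else {
      tab <- proportion_table(fits)
      tab[, p_iq_vs_res := round(unlist(pvals), 4)]
      tab
    }
  })

  ## ---- write outputs ----------------------------------------------------
  outputs <- list(table1 = table1, table2 = table2, table3 = table3,
                  grids = grids)
  for (nm in names(outputs)) {
    path <- file.path(config$outdir, paste0(nm, ".csv"))
    fwrite(outputs[[nm]], path, na = "")
    manifest$outputs[[paste0(nm, ".csv")]] <-
      list(rows = nrow(outputs[[nm]]),
           md5 = unname(tools::md5sum(path)))
  }
  manifest$stages$table2 <- list(n_rows = nrow(table2))
  manifest$stages$table3 <- list(n_rows = nrow(table3))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .log_line(log_path, "pipeline complete")
  structure(manifest, class = "run_manifest")
}

#' Reference worked-example tables
#'
#' Published summary values from the Swedish national-registry study of
#' GAEA and family genetic risk that this package models: lifetime
#' prevalence counts (cases and cohort size) and male mediation effects
#' (total, direct, indirect via IQ, indirect via resilience). Used to
#' exercise the reporting arithmetic ([prevalence_pct()],
#' [mediation_proportions()]) against printed values.
#'
#' @param which `"prevalence"` or `"mediation"`.
#' @return data.table.
#' @export
reference_table <- function(which = c("prevalence", "mediation")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0("registry_reference_", which, ".csv"),
                   package = "gaeamod", mustWork = TRUE)
  fread(f)
}
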