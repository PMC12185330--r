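#!/usr/bin/env Rscript

## Thin command-line wrapper over the gaeamod functions.
##
##   Rscript scripts/pipeline.R simulate --founders 2000 --seed 1 --outdir bundle/
##   Rscript scripts/pipeline.R score    --bundle bundle/ --seed 1 --outdir scores/
##   Rscript scripts/pipeline.R report   --bundle bundle/ --seed 1 --outdir out/
##   Rscript scripts/pipeline.R all      --founders 2000 --seed 1 --outdir out/
##
## `report` runs scoring, correlation, hazard and mediation stages on an
## existing bundle; `all` simulates first.

suppressMessages({
  library(optparse)
  library(gaeamod)
  library(data.table)
})

args <- commandArgs(trailingOnly = TRUE)
cmd <- if (length(args) >= 1) args[1] else "help"
parser <- OptionParser(option_list = list(
  make_option("--founders", type = "integer", default = 2000L,
              help = "founder couples for simulation [default %default]"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--bundle", type = "character", default = NULL,
              help = "directory holding a written bundle"),
  make_option("--outdir", type = "character", default = "gaeamod_out"),
  make_option("--disorders", type = "character",
              default = paste(DISORDER_CODES, collapse = ",")),
  make_option("--sex", type = "character", default = "all"),
  make_option("--cohort-split", action = "store_true", default = FALSE,
              dest = "cohort_split"),
  make_option("--n-boot", type = "integer", default = 0L, dest = "n_boot")
))
opts <- parse_args(parser, args = args[-1])
disorders <- strsplit(opts$disorders, ",")[[1]]

if (cmd == "simulate") {
  b <- simulate_population(sim_config(n_founder_couples = opts$founders,
                                      seed = opts$seed))
  write_bundle(b, opts$outdir)
  cat("bundle written to", opts$outdir, "-", nrow(b$persons), "persons,",
      nrow(b$events), "events\n")
} else if (cmd == "score") {
  if (is.null(opts$bundle)) stop("score needs --bundle")
  b <- read_bundle(opts$bundle)
  pr <- cohort_ids(b)
  lk <- relative_links(pedigree_graph(b$pedigree), pr, cohab = b$cohab)
  sc <- suppressWarnings(
    compute_all_scores(b, lk, probands = pr,
                       traits = c(disorders, "GAEA")))
  dir.create(opts$outdir, showWarnings = FALSE, recursive = TRUE)
  fwrite(sc, file.path(opts$outdir, "scores.csv"))
  cat("scores written to", file.path(opts$outdir, "scores.csv"), "\n")
} else if (cmd %in% c("report", "all")) {
  cfg <- run_config(
    sim = sim_config(n_founder_couples = opts$founders, seed = opts$seed),
    bundle_dir = if (cmd == "report") opts$bundle else NULL,
    disorders = disorders, sex = opts$sex,
    cohort_split = opts$cohort_split, n_boot = opts$n_boot,
    seed = opts$seed, outdir = opts$outdir)
  if (cmd == "report" && is.null(opts$bundle)) stop("report needs --bundle")
  suppressWarnings(run_pipeline(cfg))
  cat("tables written to", opts$outdir, "\n")
} else {
  cat("usage: Rscript scripts/pipeline.R <simulate|score|report|all> [options]\n")
  print_help(parser)
}
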