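#!/usr/bin/env Rscript

# Thin command-line wrapper over the parage package.  Subcommands operate
# on the delimited intermediate files so each stage can be re-run alone:
#
#   Rscript scripts/pipeline.R simulate --n 90000 --mode direct --seed 1 --dir cohort/
#   Rscript scripts/pipeline.R build    --dir cohort/ --outdir work/
#   Rscript scripts/pipeline.R fit     --data work/outcome_9.csv --out work/fit_9.json
#   Rscript scripts/pipeline.R curves  --data work/outcome_9.csv --out work/curves_9.csv
#   Rscript scripts/pipeline.R onset   --data work/outcome_9.csv --out work/onset_9.json
#   Rscript scripts/pipeline.R impact  --data work/outcome_9.csv --out work/impact_9.json
#   Rscript scripts/pipeline.R report  --dir cohort/ --outdir results/
#
# All messages go to stderr with --verbose; outputs are CSV/JSON.

suppressMessages({
  library(optparse)
  library(parage)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1L) {
  stop("usage: pipeline.R <simulate|build|fit|curves|onset|impact|report> [options]",
       call. = FALSE)
}
cmd <- args[[1]]
rest <- args[-1]

common <- list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--verbose", action = "store_true", default = FALSE)
)
opt <- function(...) parse_args(OptionParser(option_list = c(list(...), common)),
                                args = rest)

strata_default <- "sex,education,mother_birthyear_quartile,father_birthyear_quartile"
split_csv <- function(x) strsplit(x, ",")[[1]]

read_outcome_csv <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = ""))
}
wj <- function(x, path) jsonlite::write_json(
  x, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)

if (cmd == "simulate") {
  o <- opt(make_option("--n", type = "integer", default = 90000L),
           make_option("--mode", type = "character", default = "frailty"),
           make_option("--dir", type = "character", default = "cohort"))
  cfg <- generator_config(n_persons = o$n, mode = o$mode, seed = o$seed)
  coh <- generate_cohort(cfg)
  write_cohort(coh, o$dir)
  if (o$verbose) message("wrote cohort (", nrow(coh$persons), " persons) to ", o$dir)

} else if (cmd == "build") {
  o <- opt(make_option("--dir", type = "character", default = "cohort"),
           make_option("--outdir", type = "character", default = "work"),
           make_option("--variant", type = "character", default = "mean"),
           make_option("--threshold", type = "double", default = 55),
           make_option("--no-threshold", action = "store_true",
                       default = FALSE, dest = "no_threshold"),
           make_option("--exclude-alive", action = "store_true",
                       default = FALSE, dest = "exclude_alive"))
  coh <- read_cohort(o$dir)
  ex <- apply_exclusions(coh$persons, coh$parents,
                         parental_age_threshold =
                           if (o$no_threshold) NULL else o$threshold,
                         exclude_alive_parents = o$exclude_alive)
  expo <- build_exposure(ex$persons, ex$parents, variant = o$variant)
  dir.create(o$outdir, recursive = TRUE, showWarnings = FALSE)
  wj(unclass(ex$ledger), file.path(o$outdir, "exclusion_ledger.json"))
  for (oc in c("all_cause_death", icd_chapters()$chapter)) {
    ds <- build_outcome_dataset(ex$persons, ex$parents, coh$diagnoses,
                                expo, oc)
    data.table::fwrite(ds, file.path(o$outdir,
                                     paste0("outcome_", oc, ".csv")), na = "")
    if (o$verbose) message("outcome ", oc, ": ",
                           sum(ds$status == "event"), " events")
  }

} else if (cmd == "fit") {
  o <- opt(make_option("--data", type = "character"),
           make_option("--out", type = "character", default = "fit.json"),
           make_option("--strata", type = "character",
                       default = strata_default))
  ds <- read_outcome_csv(o$data)
  fits <- list(crude = cox_fit(ds),
               stratified = cox_fit(ds, strata = split_csv(o$strata)))
  wj(lapply(fits, function(f) list(
    beta = unname(f$beta), se = unname(f$se), hr = unname(f$hr),
    ci95 = list(low = unname(f$ci95["low", ]), high = unname(f$ci95["high", ])),
    p_value = unname(f$p_value), loglik = f$loglik, n = f$n,
    n_events = f$n_events, n_strata = f$n_strata,
    iterations = f$iterations, converged = f$converged)), o$out)
  if (o$verbose) message("HR crude ", round(fits$crude$hr, 4),
                         ", stratified ", round(fits$stratified$hr, 4))

} else if (cmd == "curves") {
  o <- opt(make_option("--data", type = "character"),
           make_option("--out", type = "character", default = "curves.csv"))
  ds <- read_outcome_csv(o$data)
  data.table::fwrite(as.data.frame(nelson_aalen(ds)), o$out)

} else if (cmd == "onset") {
  o <- opt(make_option("--data", type = "character"),
           make_option("--out", type = "character", default = "onset.json"),
           make_option("--alpha", type = "double", default = 0.001),
           make_option("--grid-min", type = "integer", default = 40L,
                       dest = "grid_min"),
           make_option("--grid-max", type = "integer", default = 66L,
                       dest = "grid_max"))
  ds <- read_outcome_csv(o$data)
  res <- find_onset(ds, alpha = o$alpha, grid = seq(o$grid_max, o$grid_min))
  wj(list(onset_age = res$onset_age, alpha = res$alpha, trace = res$trace),
     o$out)
  if (o$verbose) message("onset age: ", res$onset_age)

} else if (cmd == "impact") {
  o <- opt(make_option("--data", type = "character"),
           make_option("--out", type = "character", default = "impact.json"),
           make_option("--resamples", type = "integer", default = 20L))
  ds <- read_outcome_csv(o$data)
  res <- estimate_impact(ds, n_resamples = o$resamples, seed = o$seed)
  wj(list(observed_events = res$observed_events,
          counterfactual_events = res$counterfactual_events,
          avoided = res$avoided, avoided_fraction = res$avoided_fraction,
          n_resamples = res$n_resamples, per_stratum = res$per_stratum),
     o$out)

} else if (cmd == "report") {
  o <- opt(make_option("--dir", type = "character", default = "cohort"),
           make_option("--outdir", type = "character", default = "results"),
           make_option("--variant", type = "character", default = "mean"),
           make_option("--threshold", type = "double", default = 55),
           make_option("--no-threshold", action = "store_true",
                       default = FALSE, dest = "no_threshold"),
           make_option("--exclude-alive", action = "store_true",
                       default = FALSE, dest = "exclude_alive"),
           make_option("--alpha", type = "double", default = 0.001),
           make_option("--resamples", type = "integer", default = 20L))
  cfg <- run_config(
    exposure_variant = o$variant,
    parental_age_threshold = if (o$no_threshold) NULL else o$threshold,
    exclude_alive_parents = o$exclude_alive,
    alpha = o$alpha, n_resamples = o$resamples, seed = o$seed,
    verbose = o$verbose)
  run_pipeline(o$dir, cfg, outdir = o$outdir)
  if (o$verbose) message("artifacts written to ", o$outdir)

} else {
  stop("unknown subcommand: ", cmd, call. = FALSE)
}
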