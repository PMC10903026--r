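#' Configuration of an analysis run
#'
#' Collects the knobs of the end-to-end analysis: the exposure variant
#' (mean / maternal / paternal attained age), the lower parental
#' attained-age threshold (`NULL` disables it for the full-range
#' sensitivity analysis), whether to exclude persons with a parent still
#' alive at the administrative cut-off, the stratification variables, the
#' onset-detection threshold, the resampling controls, and the outcomes to
#' analyse.
#'
#' @param exposure_variant `"mean"`, `"maternal"` or `"paternal"`.
#' @param parental_age_threshold lower parental age-at-death threshold
#'   (years) or `NULL`.
#' @param exclude_alive_parents sensitivity flag.
#' @param strata_vars stratification columns of the stratified Cox model
#'   (their cross-classification defines the strata).
#' @param alpha onset-detection significance threshold.
#' @param n_resamples resamples for the counterfactual estimator.
#' @param seed seed for the resampling stage.
#' @param outcomes outcomes to analyse.
#' @param admin_end_age administrative end of follow-up.
#' @param quartile_boundaries optional fixed exposure quartile boundaries.
#' @param onset_grid truncation grid for onset detection.
#' @param verbose log stage progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(exposure_variant = c("mean", "maternal", "paternal"),
                       parental_age_threshold = 55,
                       exclude_alive_parents = FALSE,
                       strata_vars = c("sex", "education",
                                       "mother_birthyear_quartile",
                                       "father_birthyear_quartile"),
                       alpha = 0.001,
                       n_resamples = 20,
                       seed = 1,
                       outcomes = c("all_cause_death",
                                    icd_chapters()$chapter),
                       admin_end_age = 66.9,
                       quartile_boundaries = NULL,
                       onset_grid = seq(66, 40),
                       verbose = FALSE) {
  cfg <- list(
    exposure_variant = match.arg(exposure_variant),
    parental_age_threshold = parental_age_threshold,
    exclude_alive_parents = isTRUE(exclude_alive_parents),
    strata_vars = strata_vars, alpha = alpha,
    n_resamples = n_resamples, seed = seed,
    outcomes = as.character(outcomes),
    admin_end_age = admin_end_age,
    quartile_boundaries = quartile_boundaries,
    onset_grid = onset_grid, verbose = isTRUE(verbose)
  )
  class(cfg) <- "run_config"
  cfg
}

log_stage <- function(verbose, ...) {
  if (verbose) message("[parage] ", sprintf(...))
}

#' Run the full analysis pipeline
#'
#' Executes, for a cohort (a `synthetic_cohort` or a directory of cohort
#' CSVs): the exclusion cascade, exposure and quartile construction, and,
#' per outcome, the crude and stratified Cox fits, quartile Nelson-Aalen
#' curves, onset detection, and the counterfactual impact estimate; then
#' the summary tables.  When `outdir` is given all artifacts are written
#' as CSV/JSON (`fit_<outcome>.json`, `curves_<outcome>.csv`,
#' `onset_<outcome>.json`, `impact_<outcome>.json`, `tables.csv`,
#' `impact_summary.csv`, `exclusion_ledger.json`, `manifest.json`); the
#' manifest records versions, seeds, per-stage row counts, and output
#' checksums, and is reproducible given the same inputs and seeds.
#'
#' @param cohort a `synthetic_cohort` or a path readable by
#'   [read_cohort()].
#' @param config a [run_config()].
#' @param outdir optional output directory.
#' @return Invisibly, a list with the ledger, exposures, per-outcome
#'   results, tables and impact summary.
#' @export
run_pipeline <- function(cohort, config = run_config(), outdir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort"))
  v <- config$verbose

  log_stage(v, "exclusions: %d persons in", nrow(cohort$persons))
  ex <- apply_exclusions(
    cohort$persons, cohort$parents,
    parental_age_threshold = config$parental_age_threshold,
    exclude_alive_parents = config$exclude_alive_parents
  )
  log_stage(v, "exclusions: %d persons retained",
            nrow(ex$persons))

  exposures <- build_exposure(ex$persons, ex$parents,
                              variant = config$exposure_variant)

  results <- list()
  for (outcome in config$outcomes) {
    oc <- as.character(outcome)
    log_stage(v, "outcome %s: building dataset", oc)
    ds <- tryCatch(
      build_outcome_dataset(ex$persons, ex$parents, cohort$diagnoses,
                            exposures, oc,
                            admin_end_age = config$admin_end_age,
                            quartile_boundaries = config$quartile_boundaries),
      error = function(e) {
        stop_parage("stage build_outcome_dataset failed for outcome '", oc,
                    "': ", conditionMessage(e))
      })
    fits <- list(
      crude = cox_fit(ds),
      stratified = cox_fit(ds, strata = config$strata_vars)
    )
    log_stage(v, "outcome %s: HR crude %.3f, stratified %.3f", oc,
              fits$crude$hr, fits$stratified$hr)
    curves <- nelson_aalen(ds)
    onset <- find_onset(ds, alpha = config$alpha, grid = config$onset_grid)
    impact <- estimate_impact(ds, n_resamples = config$n_resamples,
                              seed = config$seed)
    results[[oc]] <- list(dataset_rows = nrow(ds), n_events = fits$crude$n_events,
                          fits = fits, curves = curves, onset = onset,
                          impact = impact)
  }

  tables <- make_tables(lapply(results, `[[`, "fits"))
  summary <- impact_summary(lapply(results, `[[`, "impact"),
                            expected_outcomes = config$outcomes)

  out <- list(ledger = ex$ledger, exposures = exposures, results = results,
              tables = tables, impact_summary = summary, config = config)

  if (!is.null(outdir)) write_artifacts(out, outdir)
  invisible(out)
}

cox_fit_json <- function(fit) {
  list(beta = unname(fit$beta), se = unname(fit$se), hr = unname(fit$hr),
       ci95 = list(low = unname(fit$ci95["low", ]),
                   high = unname(fit$ci95["high", ])),
       p_value = unname(fit$p_value), loglik = fit$loglik, n = fit$n,
       n_events = fit$n_events, n_strata = fit$n_strata,
       iterations = fit$iterations, converged = fit$converged)
}

write_artifacts <- function(out, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(outdir, f), auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE)

  wj(unclass(out$ledger), "exclusion_ledger.json")
  for (oc in names(out$results)) {
    r <- out$results[[oc]]
    wj(list(outcome = oc,
            crude = cox_fit_json(r$fits$crude),
            stratified = cox_fit_json(r$fits$stratified)),
       paste0("fit_", oc, ".json"))
    cu <- as.data.frame(r$curves)
    data.table::fwrite(cu, file.path(outdir, paste0("curves_", oc, ".csv")))
    wj(list(outcome = oc, onset_age = r$onset$onset_age,
            alpha = r$onset$alpha, trace = r$onset$trace),
       paste0("onset_", oc, ".json"))
    wj(list(outcome = oc, observed_events = r$impact$observed_events,
            counterfactual_events = r$impact$counterfactual_events,
            avoided = r$impact$avoided,
            avoided_fraction = r$impact$avoided_fraction,
            n_resamples = r$impact$n_resamples,
            per_stratum = r$impact$per_stratum),
       paste0("impact_", oc, ".json"))
  }
  data.table::fwrite(out$tables, file.path(outdir, "tables.csv"))
  data.table::fwrite(out$impact_summary,
                     file.path(outdir, "impact_summary.csv"))

  files <- setdiff(list.files(outdir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("parage")),
    seed = out$config$seed,
    exposure_variant = out$config$exposure_variant,
    n_analytic = out$ledger$n_remaining[nrow(out$ledger)],
    outcome_rows = lapply(out$results, `[[`, "dataset_rows"),
    outcome_events = lapply(out$results, `[[`, "n_events"),
    checksums = as.list(tools::md5sum(file.path(outdir, sort(files))))
  )
  names(manifest$checksums) <- sort(files)
  wj(manifest, "manifest.json")
  invisible(outdir)
}

#' Hazard-ratio tables for all fitted outcomes
#'
#' Lays out the crude and stratified per-decade hazard ratios with their
#' confidence intervals and Wald p-values, one row per outcome and model,
#' mirroring the shape of the mortality and per-chapter regression tables.
#'
#' @param fits named list (by outcome) of lists with elements `crude` and
#'   `stratified`, each a [cox_fit()] result.
#' @return A data.frame with columns `outcome`, `model`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `n_events`.
#' @export
make_tables <- function(fits) {
  rows <- list()
  for (oc in names(fits)) {
    for (model in names(fits[[oc]])) {
      f <- fits[[oc]][[model]]
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, model = model,
        hr = unname(f$hr[1]), ci_low = unname(f$ci95["low", 1]),
        ci_high = unname(f$ci95["high", 1]),
        p_value = unname(f$p_value[1]), n_events = f$n_events)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
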