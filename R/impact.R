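#' Counterfactual impact of parental attained age
#'
#' Estimates the number of events that would be avoided if everyone's
#' parents had lived into the reference (fourth) attained-age quartile,
#' by stratified resampling.  Within every stratum (sex x education by
#' default), each non-reference quartile cell of size `m` is replaced by
#' `m` subjects drawn with replacement from the reference cell of the same
#' stratum, and their observed event indicators are counted; the expected
#' count is averaged over `n_resamples` draws.  Reference subjects
#' contribute their observed events unchanged.  Resampled subjects carry
#' their own follow-up, so differing censoring between quartiles is
#' inherited from the donors.
#'
#' Draws are made with one seed in a fixed order (strata sorted
#' lexicographically, then quartiles) so results are exactly reproducible.
#'
#' @param data a data.frame (typically an `outcome_dataset`).
#' @param strata character vector of stratum columns.
#' @param reference quartile level(s) forming the reference group.
#' @param n_resamples number of resamples averaged (default 20).
#' @param seed integer seed for the resampling.
#' @param quartile,status column names.
#' @return An object of class `impact_estimate`: `outcome`,
#'   `observed_events`, `counterfactual_events`, `avoided`,
#'   `avoided_fraction`, `n_resamples`, and `per_stratum` (stratum
#'   variables, quartile, m, observed, expected, mc_se).
#' @export
estimate_impact <- function(data, strata = c("sex", "education"),
                            reference = "Q4", n_resamples = 20, seed = 1,
                            quartile = "quartile", status = "status") {
  ss <- data[[status]]
  event <- if (is.numeric(ss)) ss == 1 else as.character(ss) == "event"
  q <- as.character(data[[quartile]])
  is_ref <- q %in% as.character(reference)

  s_lab <- do.call(paste, c(data[, strata, drop = FALSE], list(sep = "|")))
  strata_levels <- sort(unique(s_lab))
  q_levels <- sort(setdiff(unique(q), as.character(reference)))

  set.seed(as.integer(seed) + .stream_offsets[["impact"]])
  per <- list()
  for (s in strata_levels) {
    in_s <- s_lab == s
    donors <- event[in_s & is_ref]
    for (qq in q_levels) {
      cell <- in_s & q == qq
      m <- sum(cell)
      if (m == 0L) next
      if (length(donors) == 0L) {
        stop_parage("empty reference cell in stratum '", s,
                    "': the counterfactual is undefined there")
      }
      draws <- vapply(seq_len(n_resamples), function(r) {
        sum(donors[sample.int(length(donors), m, replace = TRUE)])
      }, numeric(1))
      per[[length(per) + 1L]] <- data.frame(
        stratum = s, quartile = qq, m = m,
        observed = sum(event[cell]),
        expected = mean(draws),
        mc_se = stats::sd(draws) / sqrt(n_resamples)
      )
    }
  }
  per_stratum <- do.call(rbind, per)

  observed <- sum(event)
  counterfactual <- sum(event[is_ref]) + sum(per_stratum$expected)
  res <- list(
    outcome = attr(data, "outcome"),
    observed_events = observed,
    counterfactual_events = counterfactual,
    avoided = observed - counterfactual,
    avoided_fraction = (observed - counterfactual) / observed,
    n_resamples = n_resamples,
    per_stratum = per_stratum
  )
  class(res) <- "impact_estimate"
  res
}

#' @export
print.impact_estimate <- function(x, ...) {
  cat("Counterfactual impact estimate\n")
  if (!is.null(x$outcome)) cat("  outcome:", x$outcome, "\n")
  cat(sprintf("  observed events: %d\n  counterfactual events: %.1f\n",
              x$observed_events, x$counterfactual_events))
  cat(sprintf("  avoided: %.1f (%.1f%% of observed), %d resamples\n",
              x$avoided, 100 * x$avoided_fraction, x$n_resamples))
  invisible(x)
}

#' Summarize impact estimates across outcomes
#'
#' Aggregates per-outcome counterfactual estimates: mortality is reported
#' on its own and hospitalization chapters are pooled by summing observed
#' and counterfactual first-time events across chapters before forming
#' the avoided fraction.  Counts are rounded to integers and fractions to
#' whole percent in the report columns; unrounded values are kept
#' alongside.
#'
#' @param estimates a list of `impact_estimate` objects.
#' @param expected_outcomes outcomes that ought to be present; missing
#'   ones are reported with a warning and the aggregate computed over
#'   those present.
#' @return A data.frame with one row per outcome plus an
#'   `all_hospitalizations` pooled row.
#' @export
impact_summary <- function(estimates,
                           expected_outcomes = c("all_cause_death",
                                                 icd_chapters()$chapter)) {
  labs <- vapply(estimates, function(e) as.character(e$outcome %||% ""),
                 character(1))
  names(estimates) <- labs
  missing <- setdiff(as.character(expected_outcomes), labs)
  if (length(missing)) {
    warning("missing outcome estimate(s): ", paste(missing, collapse = ", "),
            "; aggregate computed over present outcomes")
  }
  row_of <- function(e, label = e$outcome %||% "unknown") {
    data.frame(outcome = as.character(label),
               observed = e$observed_events,
               counterfactual = e$counterfactual_events,
               avoided = e$avoided,
               avoided_fraction = e$avoided_fraction,
               avoided_round = round(e$avoided),
               avoided_pct = round(100 * e$avoided_fraction))
  }
  rows <- lapply(estimates, row_of)
  chapters <- labs[labs != "all_cause_death"]
  if (length(chapters)) {
    obs <- sum(vapply(estimates[chapters], `[[`, numeric(1),
                      "observed_events"))
    cf <- sum(vapply(estimates[chapters], `[[`, numeric(1),
                     "counterfactual_events"))
    pooled <- list(outcome = "all_hospitalizations", observed_events = obs,
                   counterfactual_events = cf, avoided = obs - cf,
                   avoided_fraction = (obs - cf) / obs)
    rows <- c(rows, list(row_of(pooled, "all_hospitalizations")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
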