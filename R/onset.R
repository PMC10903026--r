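#' Onset of risk differences between exposure quartiles
#'
#' Locates the earliest age at which the group risk curves separate, by
#' recursively truncating follow-up and re-testing.  The first log-rank
#' test uses the complete follow-up; if it is significant at `alpha`, the
#' test is repeated with follow-up administratively censored one grid step
#' earlier, and so on until a non-significant test is obtained.  The last
#' age with a significant test is the onset of the risk difference; if the
#' first test is already non-significant there is no onset.  Calendar
#' year-ends are collapsed to integer ages (everyone is born the same
#' year), and each test is computed from scratch at its truncation.  The
#' sequence is uncorrected for multiplicity, as a descriptive — not
#' inferential — localization.
#'
#' @param data a data.frame (typically an `outcome_dataset`).
#' @param group grouping column (default exposure quartile).
#' @param alpha significance threshold (default 0.001).
#' @param grid strictly decreasing ages (years) at which follow-up is
#'   truncated; the first entry labels the full-follow-up test.
#' @param baseline_age start of follow-up; truncation at age `a` censors
#'   at time `a - baseline_age`.
#' @param time,status column names; see [cox_fit()].
#' @return An object of class `onset_result`: `outcome`, `onset_age`
#'   (`NA` if none), `trace` (truncation_age, statistic, p_value),
#'   `alpha`.
#' @export
find_onset <- function(data, group = "quartile", alpha = 0.001,
                       grid = seq(66, 40), baseline_age = 39,
                       time = "time", status = "status") {
  if (!length(grid) || any(diff(grid) >= 0)) {
    stop_parage("grid must be non-empty and strictly decreasing")
  }
  if (!(alpha > 0 && alpha < 1)) stop_parage("alpha must be in (0, 1)")

  trace <- data.frame(truncation_age = numeric(0), statistic = numeric(0),
                      p_value = numeric(0))
  onset <- NA_real_
  for (i in seq_along(grid)) {
    mt <- if (i == 1L) NULL else grid[i] - baseline_age
    lr <- logrank_k(data, group = group, time = time, status = status,
                    max_time = mt)
    trace[i, ] <- c(grid[i], lr$statistic, lr$p_value)
    if (lr$p_value >= alpha) break
    onset <- grid[i]
  }
  res <- list(outcome = attr(data, "outcome"), onset_age = onset,
              trace = trace, alpha = alpha)
  class(res) <- "onset_result"
  res
}

#' @export
print.onset_result <- function(x, ...) {
  cat("Onset of risk differences (recursive truncated log-rank)\n")
  if (!is.null(x$outcome)) cat("  outcome:", x$outcome, "\n")
  cat(sprintf("  alpha = %g, tests run = %d\n", x$alpha, nrow(x$trace)))
  if (is.na(x$onset_age)) {
    cat("  no onset: first test non-significant\n")
  } else {
    cat(sprintf("  onset age: %g years\n", x$onset_age))
  }
  invisible(x)
}
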