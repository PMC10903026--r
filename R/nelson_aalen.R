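#' Nelson-Aalen cumulative hazard curves by group
#'
#' Estimates the cause-specific cumulative hazard per group as the step
#' function accumulating `d_i / n_i` at each distinct event time (`d_i`
#' events among `n_i` at risk).  Competing events and censorings leave the
#' risk set at their times without contributing increments.
#'
#' @param data a data.frame (typically an `outcome_dataset`).
#' @param group_by name of the grouping column; `NULL` for a single
#'   overall curve.
#' @param time,status column names; see [cox_fit()].
#' @return An object of class `nelson_aalen`: a named list of per-group
#'   data.frames with columns `time`, `n_risk`, `n_event`, `cumhaz`.
#'   Groups with zero subjects are omitted with a warning.
#' @export
nelson_aalen <- function(data, group_by = "quartile", time = "time",
                         status = "status") {
  tt <- data[[time]]
  ss <- data[[status]]
  event <- if (is.numeric(ss)) ss == 1 else as.character(ss) == "event"
  if (!length(tt)) stop_parage("empty dataset")
  g <- if (is.null(group_by)) factor(rep("all", length(tt))) else
    as.factor(data[[group_by]])
  empty <- tabulate(g, nlevels(g)) == 0L
  if (any(empty)) {
    warning("omitting empty group(s): ",
            paste(levels(g)[empty], collapse = ", "))
    g <- droplevels(g)
  }

  curves <- lapply(levels(g), function(lev) {
    sel <- g == lev
    t_g <- tt[sel]
    e_g <- event[sel]
    dt <- sort(unique(t_g[e_g]))
    if (!length(dt)) {
      return(data.frame(time = numeric(0), n_risk = numeric(0),
                        n_event = numeric(0), cumhaz = numeric(0)))
    }
    st <- sort(t_g)
    n_risk <- length(t_g) - findInterval(dt, st, left.open = TRUE)
    n_event <- as.numeric(table(factor(match(t_g[e_g], dt),
                                       levels = seq_along(dt))))
    data.frame(time = dt, n_risk = n_risk, n_event = n_event,
               cumhaz = cumsum(n_event / n_risk))
  })
  names(curves) <- levels(g)
  structure(curves, class = "nelson_aalen")
}

#' @export
print.nelson_aalen <- function(x, ...) {
  cat("Nelson-Aalen cumulative hazard curves\n")
  for (g in names(x)) {
    cu <- x[[g]]
    final <- if (nrow(cu)) cu$cumhaz[nrow(cu)] else 0
    cat(sprintf("  %s: %d event times, final cumulative hazard %.4f\n",
                g, nrow(cu), final))
  }
  invisible(x)
}

#' @export
as.data.frame.nelson_aalen <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(g) {
    if (!nrow(x[[g]])) return(NULL)
    cbind(group = g, x[[g]])
  }))
}
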