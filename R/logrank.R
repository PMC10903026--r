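#' k-sample log-rank test
#'
#' The standard k-sample log-rank chi-square: at every distinct event time
#' the observed group event counts are compared with their expectation
#' under the hypergeometric distribution given the margins, and the summed
#' observed-minus-expected vector is normalized by the summed
#' hypergeometric variance-covariance matrix.  Competing events and
#' censorings leave the risk sets at their times.  An optional truncation
#' administratively censors all follow-up beyond `max_time`.
#'
#' @param data a data.frame (typically an `outcome_dataset`).
#' @param group name of the grouping column (default the exposure
#'   quartile).
#' @param time,status column names; see [cox_fit()] for the status
#'   convention.
#' @param max_time optional truncation (years since baseline): rows with
#'   `time > max_time` are censored at `max_time`.
#' @return An object of class `logrank_result`: `statistic`, `df`
#'   (non-empty groups minus 1), `p_value`, and `per_group` (group, n,
#'   observed, expected).
#' @export
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4, 5, 6), status = c(1, 1, 1, 1, 1, 0),
#'                 g = rep(c("a", "b"), 3))
#' logrank_k(d, group = "g")
logrank_k <- function(data, group = "quartile", time = "time",
                      status = "status", max_time = NULL) {
  tt <- data[[time]]
  ss <- data[[status]]
  g <- data[[group]]
  if (is.null(tt) || is.null(ss) || is.null(g)) {
    stop_parage("time/status/group columns not found")
  }
  event <- if (is.numeric(ss)) ss == 1 else as.character(ss) == "event"
  if (!is.null(max_time)) {
    trunc <- tt > max_time
    event[trunc] <- FALSE
    tt[trunc] <- max_time
  }
  g <- factor(g)
  g <- droplevels(g)
  k <- nlevels(g)
  if (k < 2L) stop_parage("need at least 2 non-empty groups")
  n_g <- tabulate(g, k)

  per_group <- data.frame(group = levels(g), n = n_g,
                          observed = 0, expected = 0)
  if (!any(event)) {
    warning("no events in any group; statistic 0")
    res <- list(statistic = 0, df = k - 1L, p_value = 1,
                per_group = per_group)
    class(res) <- "logrank_result"
    return(res)
  }

  dt <- sort(unique(tt[event]))
  m <- length(dt)
  ## events per group per distinct event time
  D <- table(factor(match(tt[event], dt), levels = seq_len(m)), g[event])
  D <- matrix(as.numeric(D), m, k)
  ## at-risk counts per group at each event time
  N <- vapply(seq_len(k), function(j) {
    st <- sort(tt[as.integer(g) == j])
    n_g[j] - findInterval(dt, st, left.open = TRUE)
  }, numeric(m))
  N <- matrix(N, m, k)

  d_t <- rowSums(D)
  n_t <- rowSums(N)
  P <- N / n_t
  E <- d_t * P
  cc <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  V <- diag(colSums(cc * P), k) - crossprod(P, cc * P)

  O <- colSums(D)
  OE <- O - colSums(E)
  u <- OE[-k]
  Vm <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(u %*% solve(Vm, u)), error = function(e) {
    ## near-singular covariance (e.g. tiny risk sets): generalized inverse
    sv <- svd(V)
    pos <- sv$d > max(sv$d) * 1e-12
    drop(t(OE) %*% sv$v[, pos, drop = FALSE] %*%
           ((1 / sv$d[pos]) * t(sv$u[, pos, drop = FALSE])) %*% OE)
  })
  df <- k - 1L
  per_group$observed <- as.numeric(O)
  per_group$expected <- as.numeric(colSums(E))

  res <- list(statistic = max(stat, 0), df = df,
              p_value = stats::pchisq(max(stat, 0), df, lower.tail = FALSE),
              per_group = per_group)
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("k-sample log-rank test: chi-square = %.4g, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  print(x$per_group, row.names = FALSE, digits = 5)
  invisible(x)
}
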