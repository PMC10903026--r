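#' Stratified Cox proportional-hazards regression
#'
#' Maximizes the stratified Cox partial likelihood (the sum over strata of
#' within-stratum partial log-likelihoods) for one or more covariates by
#' Newton-Raphson with the Efron correction for tied event times.  The
#' crude model is the special case of no stratification.  With a single
#' per-decade exposure covariate, `exp(beta)` is the hazard ratio per
#' decade of mean parental attained age.
#'
#' Newton-Raphson starts at zero, declares convergence when the score norm
#' falls below `score_tol` or the relative log-likelihood change below
#' `loglik_tol`, halves the step on any log-likelihood decrease, and gives
#' up (flagged, last iterate returned) after `max_iter` iterations.
#'
#' @param data a data.frame (typically an `outcome_dataset`).
#' @param covariate name(s) of the covariate column(s).
#' @param strata optional character vector of stratification columns;
#'   strata are their cross-classification.
#' @param time,status names of the time and status columns.  `status` may
#'   be the `event`/`competing`/`censored` factor (only `"event"` counts
#'   as an event; competing events censor at their time) or a 0/1
#'   indicator.
#' @param init starting value(s) for the coefficients.
#' @param max_iter,score_tol,loglik_tol iteration controls.
#' @return An object of class `cox_fit`: `beta`, `se`, `hr`,
#'   `ci95` (rows `low`/`high`), `p_value` (Wald), `loglik`, `n`,
#'   `n_events`, `n_strata`, `iterations`, `converged`.
#' @export
#' @examples
#' d <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 1, 0),
#'                 x = c(1, 0, 1, 0))
#' cox_fit(d, covariate = "x")
cox_fit <- function(data, covariate = "exposure_decades", strata = NULL,
                    time = "time", status = "status", init = 0,
                    max_iter = 25L, score_tol = 1e-9, loglik_tol = 1e-12) {
  tt <- data[[time]]
  ss <- data[[status]]
  if (is.null(tt) || is.null(ss)) stop_parage("time/status columns not found")
  event <- if (is.numeric(ss)) ss == 1 else as.character(ss) == "event"
  if (anyNA(tt) || anyNA(event)) stop_parage("missing time or status")
  if (any(tt <= 0)) stop_parage("times must be positive")

  X <- as.matrix(data[, covariate, drop = FALSE])
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (anyNA(X)) stop_parage("missing covariate values")

  sid <- if (is.null(strata) || !length(strata)) {
    rep(1L, nrow(data))
  } else {
    as.integer(interaction(data[, strata, drop = FALSE], drop = TRUE))
  }
  if (sum(event) == 0L) stop_parage("no events in the data")

  ## per-stratum precomputation (sorting, tie structure); strata without
  ## events contribute nothing to the partial likelihood
  prep <- list()
  for (s in unique(sid)) {
    rows <- which(sid == s)
    if (!any(event[rows])) next
    prep[[length(prep) + 1L]] <-
      cox_prep_stratum(tt[rows], event[rows], X[rows, , drop = FALSE])
  }
  n_strata <- length(unique(sid))

  ## index pairs for the p(p+1)/2 second-moment columns
  ij <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  vech2mat <- function(v) {
    M <- matrix(0, p, p)
    M[ij] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }

  eval_pl <- function(beta, derivs = TRUE) {
    ll <- 0
    U <- numeric(p)
    I <- numeric(p * (p + 1) / 2)
    for (st in prep) {
      eta <- drop(st$X %*% beta)
      eta <- eta - mean(eta)   # numerical stabilization; PL is shift-invariant
      w <- exp(eta)
      A0 <- cumsum(w)[st$row_end_ev]
      s0 <- rowsum(w[st$ev], st$egi)[, 1]
      denom <- A0 - st$frac * s0[st$egi]
      ll <- ll + sum(eta[st$ev]) - sum(log(denom))
      if (!derivs) next
      wX <- w * st$X
      A1 <- colcumsum(wX)[st$row_end_ev, , drop = FALSE]
      s1 <- rowsum(wX[st$ev, , drop = FALSE], st$egi)
      num1 <- A1 - st$frac * s1[st$egi, , drop = FALSE]
      r1 <- num1 / denom
      U <- U + colSums(st$X[st$ev, , drop = FALSE]) - colSums(r1)
      wXX <- w * st$XX
      A2 <- colcumsum(wXX)[st$row_end_ev, , drop = FALSE]
      s2 <- rowsum(wXX[st$ev, , drop = FALSE], st$egi)
      num2 <- A2 - st$frac * s2[st$egi, , drop = FALSE]
      I <- I + colSums(num2 / denom)
      I <- I - as.numeric(crossprod(r1)[ij])
      ## note: subtracting crossprod inside the loop keeps I as vech
    }
    list(ll = ll, U = U, I = vech2mat(I))
  }

  beta <- rep_len(as.numeric(init), p)
  cur <- eval_pl(beta)
  if (!all(is.finite(cur$I)) || any(diag(cur$I) < 1e-12)) {
    stop_parage("degenerate input: covariate has no variation within ",
                "any risk set")
  }
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$I, cur$U), error = function(e) {
      stop_parage("degenerate input: singular information matrix")
    })
    new_beta <- beta + step
    new <- eval_pl(new_beta)
    halvings <- 0L
    while (new$ll < cur$ll && halvings < 20L) {
      halvings <- halvings + 1L
      step <- step / 2
      new_beta <- beta + step
      new <- eval_pl(new_beta)
    }
    rel <- abs(new$ll - cur$ll) / (abs(cur$ll) + 1e-300)
    beta <- new_beta
    cur <- new
    if (sqrt(sum(cur$U^2)) < score_tol || rel < loglik_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("cox_fit did not converge in ", max_iter,
            " iterations; returning last iterate")
  }

  cov_beta <- solve(cur$I)
  se <- sqrt(diag(cov_beta))
  z <- 1.959964
  names(beta) <- names(se) <- colnames(X)
  fit <- list(
    beta = beta, se = se, hr = exp(beta),
    ci95 = rbind(low = exp(beta - z * se), high = exp(beta + z * se)),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    loglik = cur$ll, n = nrow(data), n_events = sum(event),
    n_strata = n_strata, iterations = iter, converged = converged,
    score = cur$U
  )
  class(fit) <- "cox_fit"
  fit
}

colcumsum <- function(m) {
  if (nrow(m) == 1L) return(m)
  apply(m, 2, cumsum)
}

## sort a stratum by decreasing time and record the tie/event structure
## needed by the Efron partial-likelihood sums
cox_prep_stratum <- function(time, event, X) {
  o <- order(time, decreasing = TRUE)
  t_s <- time[o]
  ev <- which(event[o])
  X_s <- X[o, , drop = FALSE]
  grp <- cumsum(!duplicated(t_s))
  grp_end <- cumsum(tabulate(grp))
  eg <- grp[ev]
  egi <- match(eg, unique(eg))
  d_tab <- tabulate(egi)
  p <- ncol(X)
  ij <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XX <- X_s[, ij[, 1], drop = FALSE] * X_s[, ij[, 2], drop = FALSE]
  list(
    X = X_s, XX = XX, ev = ev,
    row_end_ev = grp_end[grp][ev],
    egi = egi,
    frac = (sequence(d_tab) - 1) / rep(d_tab, d_tab)
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (Efron ties)\n")
  cat(sprintf("  n = %d, events = %d, strata = %d, iterations = %d%s\n",
              x$n, x$n_events, x$n_strata, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    ci_low = x$ci95["low", ], ci_high = x$ci95["high", ],
                    p = format.pval(x$p_value, digits = 3))
  print(tab, digits = 4)
  invisible(x)
}
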