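# Independent brute-force oracles used across tests.  These deliberately
# re-derive quantities from first principles (loops, closed forms) and
# share no code with the package implementation.

## Cox partial log-likelihood by direct risk-set enumeration (no ties,
## single covariate) -- the Breslow/Efron distinction vanishes without ties
oracle_coxpl <- function(beta, time, status, x) {
  s <- 0
  for (i in which(status == 1)) {
    risk <- time >= time[i]
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

oracle_cox_beta <- function(time, status, x, interval = c(-8, 8)) {
  stats::optimize(oracle_coxpl, interval, time = time, status = status,
                  x = x, maximum = TRUE, tol = 1e-10)$maximum
}

## k-sample log-rank by per-event-time tabulation
oracle_logrank <- function(time, status, g) {
  g <- factor(g)
  k <- nlevels(g)
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in sort(unique(time[status == 1]))) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(status == 1 & time == t)
    for (j in seq_len(k)) {
      n_j <- sum(at_risk & g == levels(g)[j])
      d_j <- sum(status == 1 & time == t & g == levels(g)[j])
      O[j] <- O[j] + d_j
      E[j] <- E[j] + d_t * n_j / n_t
      for (h in seq_len(k)) {
        n_h <- sum(at_risk & g == levels(g)[h])
        cc <- if (n_t > 1) d_t * (n_t - d_t) / (n_t - 1) else 0
        V[j, h] <- V[j, h] +
          cc * (n_j / n_t) * ((j == h) - n_h / n_t)
      }
    }
  }
  u <- (O - E)[-k]
  stat <- drop(u %*% solve(V[-k, -k, drop = FALSE], u))
  list(O = O, E = E, V = V, stat = stat)
}

## plug-in expectation of the counterfactual estimator:
## sum over strata/quartile cells of m * (reference event fraction)
oracle_impact_plugin <- function(data, strata = c("sex", "education"),
                                 reference = "Q4") {
  event <- as.character(data$status) == "event"
  q <- as.character(data$quartile)
  s <- do.call(paste, c(data[, strata, drop = FALSE], list(sep = "|")))
  cf <- sum(event[q %in% reference])
  for (ss in unique(s)) {
    p_ref <- mean(event[s == ss & q %in% reference])
    for (qq in setdiff(unique(q), reference)) {
      m <- sum(s == ss & q == qq)
      cf <- cf + m * p_ref
    }
  }
  obs <- sum(event)
  list(observed = obs, counterfactual = cf,
       avoided_fraction = (obs - cf) / obs)
}

## tiny hand-built analysis cohort used by builder tests: four persons
## with distinct exposures, one diagnosed with I21 at 45 and dead at 60
toy_cohort <- function() {
  parents <- data.frame(
    id = 101:108,
    sex = rep(c("F", "M"), 4),
    birth_year = c(1925, 1922, 1926, 1921, 1924, 1923, 1927, 1920),
    death_age = c(70, 75, 80, 85, 90, 95, 60, 65),
    alive_at_admin = 0L,
    attained_age = c(70, 75, 80, 85, 90, 95, 60, 65)
  )
  persons <- data.frame(
    id = 1:4, sex = c("M", "F", "M", "F"), birth_year = 1953L,
    education = c(1L, 2L, 3L, 2L),
    mother_id = c(101L, 103L, 105L, 107L),
    father_id = c(102L, 104L, 106L, 108L),
    death_age = c(60, NA, NA, NA),
    emigration_age = c(NA, NA, 50, NA)
  )
  diagnoses <- data.frame(
    person_id = c(1L, 3L),
    age_at_admission = c(45, 55),
    code_system = "ICD10",
    code = c("I21", "I50")
  )
  list(persons = persons, parents = parents, diagnoses = diagnoses)
}

## standard small direct-mode analysis dataset builder
make_dataset <- function(cfg, outcome = "all_cause_death", ...) {
  coh <- generate_cohort(cfg)
  ex <- apply_exclusions(coh$persons, coh$parents)
  expo <- build_exposure(ex$persons, ex$parents)
  build_outcome_dataset(ex$persons, ex$parents, coh$diagnoses, expo,
                        outcome, ...)
}

## generator config with record artifacts switched off
clean_config <- function(...) {
  generator_config(..., frac_missing_education = 0, frac_missing_parent = 0,
                   frac_prebaseline_death = 0,
                   frac_prebaseline_emigration = 0,
                   overage_record_rate = 0)
}
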