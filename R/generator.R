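#' Configuration for the synthetic two-generation registry cohort
#'
#' Builds the parameter set for the synthetic-data generator.  The defaults
#' describe a single-year birth cohort of 90,000 persons followed from age
#' 39 until administrative end of follow-up at age 66.9, with two linked
#' parents per person whose lifespans follow a shared gamma-frailty
#' Gompertz-Makeham model, three education levels, emigration, and
#' first-time hospitalization in the ten studied ICD-10 chapters.
#'
#' Three generating modes are supported:
#' \describe{
#'   \item{`"direct"`}{Offspring hazards depend log-linearly on the mean
#'     parental attained age: outcome `j` has hazard
#'     `base_j * exp(theta_j * (A - mean(A)) / 10)`, so `exp(theta_j)` is
#'     the true cause-specific hazard ratio per decade.  Administrative
#'     censoring of parents is disabled so the exposure is exact.}
#'   \item{`"frailty"`}{Each family draws a frailty `Z ~ Gamma(shape = k,
#'     mean = 1)` acting multiplicatively on both parents' mortality rates
#'     and (raised to `frailty_power`, normalized to mean 1) on all
#'     offspring hazards, producing inherited lifespan variation without
#'     any directly encoded exposure effect.}
#'   \item{`"null"`}{All exposure and frailty effects on offspring are
#'     switched off; every downstream hazard ratio is 1 by construction.}
#' }
#'
#' The default per-decade hazard ratios (`exp(theta)`) and baseline rates
#' constitute the calibrated study scenario: an all-cause mortality HR of
#' 0.78 per decade with roughly 9\% cumulative mortality over the 27.9-year
#' window, and per-chapter HRs between 0.80 and 0.93 with first-event
#' fractions between about 4\% and 17\%.
#'
#' @param n_persons number of index persons.
#' @param mode generating mode, see Details.
#' @param seed integer seed; all randomness derives from it through fixed
#'   stream offsets (parents, demographics, event times, emigration,
#'   record artifacts).
#' @param theta_mortality log hazard ratio per decade of mean parental
#'   attained age for offspring all-cause mortality (direct mode).
#' @param theta_chapter named numeric vector, chapter -> log HR per decade.
#'   Only chapters named here (plus `all_cause_death` in
#'   `offspring_base_hazards`) are generated.
#' @param frailty_shape gamma shape `k` of the family frailty (mean fixed
#'   at 1, variance `1/k`); `Inf` means no heterogeneity.
#' @param gompertz_a,gompertz_b,makeham_c baseline parental mortality
#'   `h(x) = Z * a * exp(b x) + c` per year from birth.  The Makeham term
#'   `c` controls the fraction of premature (< 55) parental deaths.
#' @param offspring_base_hazards named per-year constant baseline rates for
#'   `all_cause_death` and the generated chapters over ages 39-67.
#' @param frailty_power exponent `w` applied to the family frailty in the
#'   offspring hazards (frailty mode).
#' @param effect_onset_age optional age (years) before which the exposure
#'   effect on offspring hazards is switched off; used for change-point
#'   experiments.  `NULL` means the effect acts from baseline.
#' @param education_probs probabilities of the three education levels
#'   (elementary / upper secondary / post-secondary); must sum to 1.
#' @param sex_prob_male probability that an index person is male.
#' @param emigration_rate per-year emigration (censoring) rate.
#' @param admin_end_age administrative end of follow-up (years).
#' @param parental_admin_censor_age_offset age of the index cohort at the
#'   parental mortality-data cut-off, so a parent's administrative censor
#'   age is this offset plus their age at the index person's birth.
#' @param fraction_parent_alive_target intended fraction of parents still
#'   alive at the administrative cut-off (approximately 0.10 under the
#'   default calibration; recorded for reference, not enforced).
#' @param mother_age_at_birth,father_age_at_birth length-4 vectors
#'   `(mean, sd, min, max)` of the parent's age at the index birth.
#' @param couple_copula_rho Gaussian-copula correlation between the two
#'   parents' lifespans beyond the shared family frailty (default 0: the
#'   only within-couple dependence is the shared frailty).
#' @param frac_missing_education,frac_missing_parent,frac_prebaseline_death,frac_prebaseline_emigration
#'   fractions of index persons carrying record artifacts that exercise
#'   the exclusion cascade.
#' @param overage_record_rate rate of erroneous parental death records
#'   above 115 years (register-error analogue).
#' @param round_ages_to_days if `TRUE`, offspring event ages are rounded
#'   to whole days, creating ties that exercise the Efron correction.
#' @param icd9_until_age admissions before this age are coded in ICD-9.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_persons = 90000,
                             mode = c("frailty", "direct", "null"),
                             seed = 1,
                             theta_mortality = log(0.78),
                             theta_chapter = c(
                               "1" = log(0.86), "2" = log(0.93),
                               "4" = log(0.83), "5" = log(0.80),
                               "6" = log(0.86), "9" = log(0.80),
                               "10" = log(0.86), "11" = log(0.90),
                               "13" = log(0.91), "14" = log(0.90)),
                             frailty_shape = 6,
                             gompertz_a = 1.35e-5,
                             gompertz_b = 0.105,
                             makeham_c = 3e-4,
                             offspring_base_hazards = c(
                               all_cause_death = 0.00338,
                               "1" = 0.00201, "2" = 0.00607, "4" = 0.00164,
                               "5" = 0.00265, "6" = 0.00211, "9" = 0.00688,
                               "10" = 0.00303, "11" = 0.00670,
                               "13" = 0.00551, "14" = 0.00429),
                             frailty_power = 1,
                             effect_onset_age = NULL,
                             education_probs = c(21216, 41260, 27212) / 89688,
                             sex_prob_male = 0.513,
                             emigration_rate = 0.0015,
                             admin_end_age = 66.9,
                             parental_admin_censor_age_offset = 68,
                             fraction_parent_alive_target = 0.10,
                             mother_age_at_birth = c(mean = 26.5, sd = 6,
                                                     min = 14, max = 45),
                             father_age_at_birth = c(mean = 29.5, sd = 6.5,
                                                     min = 16, max = 60),
                             couple_copula_rho = 0,
                             frac_missing_education = 0.010,
                             frac_missing_parent = 0.008,
                             frac_prebaseline_death = 0.004,
                             frac_prebaseline_emigration = 0.004,
                             overage_record_rate = 3e-4,
                             round_ages_to_days = FALSE,
                             icd9_until_age = 44) {
  mode <- match.arg(mode)
  cfg <- list(
    n_persons = n_persons, mode = mode, seed = seed,
    theta_mortality = theta_mortality, theta_chapter = theta_chapter,
    frailty_shape = frailty_shape, gompertz_a = gompertz_a,
    gompertz_b = gompertz_b, makeham_c = makeham_c,
    offspring_base_hazards = offspring_base_hazards,
    frailty_power = frailty_power, effect_onset_age = effect_onset_age,
    education_probs = education_probs, sex_prob_male = sex_prob_male,
    emigration_rate = emigration_rate, admin_end_age = admin_end_age,
    parental_admin_censor_age_offset = parental_admin_censor_age_offset,
    fraction_parent_alive_target = fraction_parent_alive_target,
    mother_age_at_birth = mother_age_at_birth,
    father_age_at_birth = father_age_at_birth,
    couple_copula_rho = couple_copula_rho,
    frac_missing_education = frac_missing_education,
    frac_missing_parent = frac_missing_parent,
    frac_prebaseline_death = frac_prebaseline_death,
    frac_prebaseline_emigration = frac_prebaseline_emigration,
    overage_record_rate = overage_record_rate,
    round_ages_to_days = round_ages_to_days,
    icd9_until_age = icd9_until_age
  )
  if (mode == "null") {
    cfg$theta_mortality <- 0
    cfg$theta_chapter[] <- 0
    cfg$frailty_power <- 0
  }
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is_count(cfg$n_persons)) stop_parage("n_persons must be a positive integer")
  if (!is_count(abs(cfg$seed) + 1)) stop_parage("seed must be an integer")
  if (abs(sum(cfg$education_probs) - 1) > 1e-12) {
    stop_parage("education_probs must sum to 1 (within 1e-12)")
  }
  if (any(cfg$education_probs < 0)) stop_parage("education_probs must be >= 0")
  th <- c(cfg$theta_mortality, cfg$theta_chapter)
  if (any(!is.finite(th))) stop_parage("theta values must be finite")
  if (!(cfg$frailty_shape > 0)) stop_parage("frailty_shape must be > 0")
  rates <- c(cfg$gompertz_a, cfg$gompertz_b, cfg$makeham_c,
             cfg$offspring_base_hazards, cfg$emigration_rate)
  if (any(is.na(rates)) || any(rates < 0) ||
      any(!is.finite(c(cfg$gompertz_a, cfg$gompertz_b, cfg$makeham_c)))) {
    stop_parage("hazard parameters must be finite and non-negative")
  }
  if (!all(names(cfg$theta_chapter) %in% as.character(icd_chapters()$chapter))) {
    stop_parage("theta_chapter names must be studied chapter numbers")
  }
  if (abs(cfg$couple_copula_rho) >= 1) stop_parage("couple_copula_rho must be in (-1, 1)")
  invisible(cfg)
}

## invert the Gompertz-Makeham cumulative hazard
## H(x) = (aZ/b)(e^{bx} - 1) + c x  at  H(x) = e
## closed form when c = 0; otherwise Newton from the c = 0 start, which
## overshoots (H_c >= H_0) so the convex iteration descends monotonically
gm_invert <- function(e, az, b, c) {
  x <- log1p(b * e / az) / b
  if (c > 0) {
    for (i in 1:60) {
      f <- az / b * expm1(b * x) + c * x - e
      x_new <- x - f / (az * exp(b * x) + c)
      if (max(abs(x_new - x)) < 1e-10) { x <- x_new; break }
      x <- x_new
    }
  }
  x
}

#' Generate the parental generation
#'
#' Draws one family frailty `Z ~ Gamma(shape = k, mean = 1)` per index
#' person and samples both parents' death ages from the conditional hazard
#' `Z * a * exp(b * x) + c` by inversion.  Outside direct mode, parents
#' surviving past their administrative censor age (cohort age offset plus
#' the parent's age at the index birth) are flagged alive with attained age
#' equal to the censor age.  A small configurable rate of erroneous death
#' records above age 115 is injected to exercise the exclusion cascade;
#' premature deaths below 55 arise from the Makeham background term.
#'
#' @param config a [generator_config()].
#' @return A data.frame with columns `id`, `sex`, `birth_year`,
#'   `death_age`, `alive_at_admin`, `attained_age` (mothers first, then
#'   fathers; the family frailty vector is attached as attribute
#'   `"frailty"` and parents' ages at the index birth as `"age_at_birth"`).
#' @export
generate_parents <- function(config) {
  validate_generator_config(config)
  n <- config$n_persons
  set_stream(config$seed, "parents")

  Z <- if (is.finite(config$frailty_shape)) {
    stats::rgamma(n, shape = config$frailty_shape, rate = config$frailty_shape)
  } else rep(1, n)

  mab <- rtruncnorm1(n, config$mother_age_at_birth[["mean"]],
                     config$mother_age_at_birth[["sd"]],
                     config$mother_age_at_birth[["min"]],
                     config$mother_age_at_birth[["max"]])
  fab <- rtruncnorm1(n, config$father_age_at_birth[["mean"]],
                     config$father_age_at_birth[["sd"]],
                     config$father_age_at_birth[["min"]],
                     config$father_age_at_birth[["max"]])
  birth_year_m <- 1953L - as.integer(round(mab))
  birth_year_f <- 1953L - as.integer(round(fab))

  ## exponential integrated-hazard draws, optionally coupled through a
  ## Gaussian copula beyond the shared frailty
  rho <- config$couple_copula_rho
  if (rho != 0) {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    e_m <- stats::qexp(stats::pnorm(z1))
    e_f <- stats::qexp(stats::pnorm(z2))
  } else {
    e_m <- stats::rexp(n)
    e_f <- stats::rexp(n)
  }
  death_m <- gm_invert(e_m, Z * config$gompertz_a, config$gompertz_b,
                       config$makeham_c)
  death_f <- gm_invert(e_f, Z * config$gompertz_a, config$gompertz_b,
                       config$makeham_c)

  censor_m <- config$parental_admin_censor_age_offset + (1953 - birth_year_m)
  censor_f <- config$parental_admin_censor_age_offset + (1953 - birth_year_f)
  if (config$mode == "direct") {
    ## exposure must be exact: no administrative censoring of parents
    alive_m <- alive_f <- rep(FALSE, n)
  } else {
    alive_m <- death_m > censor_m
    alive_f <- death_f > censor_f
  }

  parents <- data.frame(
    id = c(n + seq_len(n), 2L * n + seq_len(n)),
    sex = rep(c("F", "M"), each = n),
    birth_year = c(birth_year_m, birth_year_f),
    death_age = c(ifelse(alive_m, NA_real_, death_m),
                  ifelse(alive_f, NA_real_, death_f)),
    alive_at_admin = as.integer(c(alive_m, alive_f)),
    attained_age = c(ifelse(alive_m, censor_m, death_m),
                     ifelse(alive_f, censor_f, death_f)),
    stringsAsFactors = FALSE
  )

  ## register-error analogue: rare death records above 115
  if (config$overage_record_rate > 0) {
    bad <- stats::runif(2L * n) < config$overage_record_rate
    if (any(bad)) {
      age_bad <- stats::runif(sum(bad), 115.5, 121)
      parents$death_age[bad] <- age_bad
      parents$attained_age[bad] <- age_bad
      parents$alive_at_admin[bad] <- 0L
    }
  }

  attr(parents, "frailty") <- Z
  attr(parents, "age_at_birth") <- cbind(mother = mab, father = fab)
  parents
}

#' Generate index persons and their diagnosis events
#'
#' Given the parent table from [generate_parents()] (same configuration),
#' samples demographics, per-outcome event ages, emigration, and record
#' artifacts for the index generation.  Event ages for each outcome are
#' drawn independently from constant baseline hazards multiplied by the
#' mode-specific factor (see [generator_config()]); only the first event
#' per chapter is kept, death truncates later diagnoses, and a diagnosis
#' at the same age as death is recorded before the death.
#'
#' @param config a [generator_config()].
#' @param parents the table returned by [generate_parents()] under the
#'   same configuration.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `persons`, `parents`, `diagnoses`, `truth` (the configuration).
#' @export
generate_offspring <- function(config, parents) {
  validate_generator_config(config)
  n <- config$n_persons
  if (nrow(parents) != 2L * n || is.null(attr(parents, "frailty"))) {
    stop_parage("parents must come from generate_parents() under the same config")
  }
  if (config$mode == "direct" && any(parents$alive_at_admin == 1L)) {
    stop_parage("direct mode requires all parents to have a death age ",
                "(alive parents disabled so the exposure is exact)")
  }
  Z <- attr(parents, "frailty")

  set_stream(config$seed, "demographics")
  sex <- ifelse(stats::runif(n) < config$sex_prob_male, "M", "F")
  education <- sample.int(3L, n, replace = TRUE, prob = config$education_probs)

  ## exposure: mean parental attained age of the two linked parents
  att_m <- parents$attained_age[seq_len(n)]
  att_f <- parents$attained_age[n + seq_len(n)]
  A <- (att_m + att_f) / 2

  outcomes <- names(config$offspring_base_hazards)
  mult <- switch(config$mode,
    direct = {
      dec <- (A - mean(A)) / 10
      th <- c(all_cause_death = config$theta_mortality, config$theta_chapter)
      sapply(outcomes, function(o) exp(th[[o]] * dec))
    },
    frailty = {
      w <- config$frailty_power
      k <- config$frailty_shape
      norm <- if (is.finite(k)) exp(lgamma(k + w) - lgamma(k) - w * log(k)) else 1
      matrix(rep(Z^w / norm, length(outcomes)), ncol = length(outcomes),
             dimnames = list(NULL, outcomes))
    },
    null = matrix(1, n, length(outcomes), dimnames = list(NULL, outcomes))
  )
  if (n == 1L) mult <- matrix(mult, nrow = 1L, dimnames = list(NULL, outcomes))

  t_end <- config$admin_end_age - 39
  set_stream(config$seed, "events")
  ev_time <- matrix(Inf, n, length(outcomes), dimnames = list(NULL, outcomes))
  for (o in outcomes) {
    base <- config$offspring_base_hazards[[o]]
    if (base <= 0) next
    e <- stats::rexp(n)
    if (is.null(config$effect_onset_age)) {
      ev_time[, o] <- e / (base * mult[, o])
    } else {
      ## piecewise-constant hazard: baseline until the onset age, the
      ## exposure-modulated rate afterwards
      t0 <- max(config$effect_onset_age - 39, 0)
      pre <- e / base
      ev_time[, o] <- ifelse(pre <= t0, pre,
                             t0 + (e - base * t0) / (base * mult[, o]))
    }
  }

  set_stream(config$seed, "emigration")
  t_emig <- if (config$emigration_rate > 0) {
    stats::rexp(n, config$emigration_rate)
  } else rep(Inf, n)

  if (config$round_ages_to_days) {
    day <- 1 / 365.25
    ev_time[] <- pmax(round(ev_time / day) * day, day)
    t_emig <- pmax(round(t_emig / day) * day, day)
  }

  t_death <- if ("all_cause_death" %in% outcomes) {
    ev_time[, "all_cause_death"]
  } else rep(Inf, n)

  death_age <- ifelse(t_death <= t_emig & t_death <= t_end,
                      39 + t_death, NA_real_)
  emigration_age <- ifelse(t_emig < t_death & t_emig <= t_end,
                           39 + t_emig, NA_real_)

  persons <- data.frame(
    id = seq_len(n), sex = sex, birth_year = 1953L,
    education = education,
    mother_id = parents$id[seq_len(n)],
    father_id = parents$id[n + seq_len(n)],
    death_age = death_age, emigration_age = emigration_age,
    stringsAsFactors = FALSE
  )

  ## first-time hospitalizations: kept if they occur on or before death
  ## (terminal admissions count for both analyses) and before emigration
  chapters <- setdiff(outcomes, "all_cause_death")
  dx <- vector("list", length(chapters))
  set_stream(config$seed, "artifacts")
  for (i in seq_along(chapters)) {
    ch <- chapters[[i]]
    t_ch <- ev_time[, ch]
    keep <- t_ch <= t_death & t_ch < t_emig & t_ch <= t_end
    if (!any(keep)) next
    age <- 39 + t_ch[keep]
    is9 <- age < config$icd9_until_age
    dx[[i]] <- data.frame(
      person_id = persons$id[keep],
      age_at_admission = age,
      code_system = ifelse(is9, "ICD9", "ICD10"),
      code = ifelse(is9,
                    sample_icd9_code(as.integer(ch), sum(keep)),
                    sample_icd10_code(as.integer(ch), sum(keep))),
      stringsAsFactors = FALSE
    )
  }
  diagnoses <- do.call(rbind, dx[!vapply(dx, is.null, logical(1))])
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(person_id = integer(0),
                            age_at_admission = numeric(0),
                            code_system = character(0), code = character(0),
                            stringsAsFactors = FALSE)
  }
  diagnoses <- diagnoses[order(diagnoses$person_id,
                               diagnoses$age_at_admission), , drop = FALSE]
  rownames(diagnoses) <- NULL

  ## record artifacts exercising the exclusion cascade (disjoint subsets)
  n_art <- floor(n * c(config$frac_prebaseline_death,
                       config$frac_prebaseline_emigration,
                       config$frac_missing_education,
                       config$frac_missing_parent))
  if (sum(n_art) > 0 && sum(n_art) < n) {
    pick <- sample.int(n, sum(n_art))
    grp <- rep.int(1:4, n_art)
    pre_d <- pick[grp == 1L]; pre_e <- pick[grp == 2L]
    mis_ed <- pick[grp == 3L]; mis_pa <- pick[grp == 4L]
    if (length(pre_d)) {
      persons$death_age[pre_d] <- stats::runif(length(pre_d), 20, 38.9)
      persons$emigration_age[pre_d] <- NA_real_
    }
    if (length(pre_e)) {
      persons$emigration_age[pre_e] <- stats::runif(length(pre_e), 18, 38.9)
      persons$death_age[pre_e] <- NA_real_
    }
    if (length(mis_ed)) persons$education[mis_ed] <- NA_integer_
    if (length(mis_pa)) {
      drop_mother <- stats::runif(length(mis_pa)) < 0.5
      persons$mother_id[mis_pa[drop_mother]] <- NA_integer_
      persons$father_id[mis_pa[!drop_mother]] <- NA_integer_
    }
    gone <- c(pre_d, pre_e)
    if (length(gone)) {
      diagnoses <- diagnoses[!(diagnoses$person_id %in% persons$id[gone]), ,
                             drop = FALSE]
    }
  }

  structure(list(persons = persons, parents = parents,
                 diagnoses = diagnoses, truth = config),
            class = "synthetic_cohort")
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_parents()] then
#' [generate_offspring()].
#'
#' @param config a [generator_config()].
#' @return A `synthetic_cohort` object.
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_persons = 500, seed = 7))
#' coh
generate_cohort <- function(config) {
  generate_offspring(config, generate_parents(config))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic two-generation cohort\n")
  cat(sprintf("  mode: %s, seed: %s\n", x$truth$mode, x$truth$seed))
  cat(sprintf("  index persons: %d, parents: %d, diagnosis events: %d\n",
              nrow(x$persons), nrow(x$parents), nrow(x$diagnoses)))
  invisible(x)
}

#' Write / read a synthetic cohort as delimited text
#'
#' `write_cohort()` writes `persons.csv`, `parents.csv`, `diagnoses.csv`
#' and `truth.json` (the generating configuration) to a directory;
#' `read_cohort()` reads them back.  The round trip is lossless and
#' re-writing a read cohort reproduces byte-identical files.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path directory to write to (created if needed).
#' @return `write_cohort()` returns the path invisibly; `read_cohort()`
#'   returns a `synthetic_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_parage("cannot create directory: ", path)
  }
  persons <- cohort$persons
  parents <- cohort$parents
  attributes(parents)[c("frailty", "age_at_birth")] <- NULL
  data.table::fwrite(persons, file.path(path, "persons.csv"), na = "")
  data.table::fwrite(parents, file.path(path, "parents.csv"), na = "")
  data.table::fwrite(cohort$diagnoses, file.path(path, "diagnoses.csv"),
                     na = "")
  truth <- unclass(cohort$truth)
  truth$theta_chapter <- as.list(truth$theta_chapter)
  truth$offspring_base_hazards <- as.list(truth$offspring_base_hazards)
  jsonlite::write_json(truth, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  rd <- function(f, cols) {
    x <- as.data.frame(data.table::fread(file.path(path, f),
                                         na.strings = ""))
    x
  }
  persons <- rd("persons.csv")
  parents <- rd("parents.csv")
  diagnoses <- rd("diagnoses.csv")
  if (nrow(diagnoses)) {
    diagnoses$code <- as.character(diagnoses$code)
    diagnoses$code_system <- as.character(diagnoses$code_system)
  }
  truth <- NULL
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) {
    raw <- jsonlite::read_json(tf, simplifyVector = TRUE)
    raw$theta_chapter <- unlist(raw$theta_chapter)
    raw$offspring_base_hazards <- unlist(raw$offspring_base_hazards)
    truth <- structure(raw, class = "generator_config")
  }
  structure(list(persons = persons, parents = parents,
                 diagnoses = diagnoses, truth = truth),
            class = "synthetic_cohort")
}
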