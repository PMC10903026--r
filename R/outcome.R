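#' Build a per-outcome survival dataset
#'
#' Turns the analysis cohort into the survival table for one outcome.
#' Follow-up runs from exact age `baseline_age` (time 0) until the first
#' of: the event of interest, death, emigration, or administrative end of
#' follow-up.  For a hospitalization outcome the event is the first
#' admission carrying a code in that ICD chapter; death and emigration are
#' competing events (`status = "competing"`, treated as censoring in
#' cause-specific fits).  For all-cause mortality death is the event and
#' emigration censors.  An admission at the same age as death is counted
#' as the admission (and the death still counts for the mortality
#' analysis).
#'
#' The continuous exposure is centred (at the sample mean by default) and
#' scaled to decades, so Cox coefficients are log hazard ratios per decade
#' of mean parental attained age.  Stratification variables (sex,
#' education, and empirical quartiles of maternal and paternal birth year)
#' are attached to every row.
#'
#' @param persons,parents tables after [apply_exclusions()].
#' @param diagnoses diagnosis table (`person_id`, `age_at_admission`,
#'   `code_system`, `code`).
#' @param exposures output of [build_exposure()].
#' @param outcome `"all_cause_death"` or a studied chapter number.
#' @param admin_end_age administrative end of follow-up (years).
#' @param baseline_age start of follow-up (years).
#' @param center reference value for the exposure; default sample mean.
#' @param quartile_boundaries passed to [assign_quartiles()] for the
#'   exposure quartile (default: empirical).
#' @return A data.frame of class `outcome_dataset` with columns
#'   `person_id`, `time` (years since baseline), `status`
#'   (`event`/`competing`/`censored`), `exposure_decades`, `quartile`,
#'   `sex`, `education`, `mother_birthyear_quartile`,
#'   `father_birthyear_quartile`; attributes `outcome`, `center`,
#'   `boundaries`.
#' @export
build_outcome_dataset <- function(persons, parents, diagnoses, exposures,
                                  outcome, admin_end_age = 66.9,
                                  baseline_age = 39, center = NULL,
                                  quartile_boundaries = NULL) {
  outcome <- as.character(outcome)
  chapters <- as.character(icd_chapters()$chapter)
  if (!outcome %in% c("all_cause_death", chapters)) {
    stop_parage("unknown outcome: ", outcome)
  }

  ie <- match(persons$id, exposures$person_id)
  if (anyNA(ie)) stop_parage("persons missing from the exposure table")
  expo <- exposures$exposure[ie]

  t_max <- admin_end_age - baseline_age
  t_death <- persons$death_age - baseline_age
  t_emig <- persons$emigration_age - baseline_age

  if (outcome == "all_cause_death") {
    has_death <- !is.na(t_death) & t_death <= pmin(t_emig, t_max, na.rm = TRUE)
    time <- pmin(t_death, t_emig, t_max, na.rm = TRUE)
    status <- ifelse(has_death, "event", "censored")
  } else {
    ## first admission in the chapter, inside the person's follow-up
    if (nrow(diagnoses)) {
      chap <- map_icd_chapter(diagnoses$code_system, diagnoses$code)
      dx <- diagnoses[!is.na(chap) & chap == as.integer(outcome), ,
                      drop = FALSE]
    } else dx <- diagnoses
    t_dx <- rep(NA_real_, nrow(persons))
    if (nrow(dx)) {
      first <- tapply(dx$age_at_admission, dx$person_id, min)
      idx <- match(persons$id, as.numeric(names(first)))
      t_dx <- unname(first[idx]) - baseline_age
      if (any(t_dx < 0, na.rm = TRUE)) {
        stop_parage("diagnosis event before entry into follow-up")
      }
    }
    ## admission on the same age as death counts as the admission
    t_compete <- pmin(t_death, t_emig, na.rm = TRUE)
    is_event <- !is.na(t_dx) & t_dx <= pmin(t_compete, t_max, na.rm = TRUE)
    time <- ifelse(is_event, t_dx, pmin(t_compete, t_max, na.rm = TRUE))
    status <- ifelse(is_event, "event",
                     ifelse(!is.na(t_compete) & t_compete <= t_max,
                            "competing", "censored"))
  }
  if (any(time <= 0, na.rm = TRUE) || anyNA(time)) {
    stop_parage("non-positive or missing follow-up time; ",
                "apply exclusions before building outcome datasets")
  }

  center <- center %||% mean(expo)
  q <- assign_quartiles(expo, quartile_boundaries)

  im <- match(persons$mother_id, parents$id)
  ip <- match(persons$father_id, parents$id)
  mq <- assign_quartiles(parents$birth_year[im])
  fq <- assign_quartiles(parents$birth_year[ip])

  out <- data.frame(
    person_id = persons$id,
    time = time,
    status = factor(status, levels = c("event", "competing", "censored")),
    exposure_decades = (expo - center) / 10,
    quartile = q,
    sex = persons$sex,
    education = persons$education,
    mother_birthyear_quartile = mq,
    father_birthyear_quartile = fq,
    stringsAsFactors = FALSE
  )
  attr(out, "outcome") <- outcome
  attr(out, "center") <- center
  attr(out, "boundaries") <- attr(q, "boundaries")
  attr(out, "admin_end_age") <- admin_end_age
  class(out) <- c("outcome_dataset", "data.frame")
  out
}
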