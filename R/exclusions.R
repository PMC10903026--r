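#' Parental attained age
#'
#' A parent's attained age is their age at death or, if still alive at the
#' administrative cut-off for parental mortality data, their age on that
#' date.
#'
#' @param death_age numeric vector of death ages (NA when alive).
#' @param alive_at_admin logical/0-1 vector: still alive at the cut-off.
#' @param admin_date_age age on the administrative cut-off date (required
#'   for alive parents).
#' @return Numeric vector of attained ages.
#' @export
#' @examples
#' attained_age(75.2, FALSE)
#' attained_age(NA, TRUE, admin_date_age = 86)
attained_age <- function(death_age, alive_at_admin, admin_date_age = NULL) {
  alive <- as.logical(alive_at_admin)
  n <- max(length(death_age), length(alive))
  death_age <- rep_len(death_age, n)
  alive <- rep_len(alive, n)
  out <- death_age
  if (any(alive)) {
    if (is.null(admin_date_age)) {
      stop_parage("alive parent with missing administrative-date age")
    }
    admin_date_age <- rep_len(admin_date_age, n)
    if (any(is.na(admin_date_age[alive]))) {
      stop_parage("alive parent with missing administrative-date age")
    }
    out[alive] <- admin_date_age[alive]
  }
  if (any(is.na(out) & !alive)) {
    stop_parage("dead parent with missing death age")
  }
  out
}

#' Apply the cohort exclusion cascade
#'
#' Applies, in order: pre-baseline emigration, death before baseline,
#' missing education, missing either parent link, any parent dead before
#' the lower attained-age threshold (default 55; `NULL` disables the step
#' for the full-range sensitivity analysis), optionally any parent still
#' alive at the administrative cut-off, and any parent with recorded
#' attained age above 115 (register-error exclusion).  Every step is
#' recorded in an exclusion ledger that conserves counts.
#'
#' @param persons,parents raw tables as produced by the generator or read
#'   from `persons.csv` / `parents.csv`.
#' @param parental_age_threshold lower threshold for parental age at death
#'   (years), or `NULL` for none.
#' @param parental_age_max maximum credible parental attained age.
#' @param exclude_alive_parents if `TRUE`, persons with a parent still
#'   alive at the administrative cut-off are removed (sensitivity
#'   analysis).
#' @param baseline_age start of follow-up (years).
#' @return A list with elements `persons`, `parents` (restricted to
#'   parents of retained persons) and `ledger` (class `exclusion_ledger`).
#' @export
apply_exclusions <- function(persons, parents,
                             parental_age_threshold = 55,
                             parental_age_max = 115,
                             exclude_alive_parents = FALSE,
                             baseline_age = 39) {
  if (anyDuplicated(persons$id)) stop_parage("duplicated person ids")
  if (anyDuplicated(parents$id)) stop_parage("duplicated parent ids")

  steps <- list()
  keep <- persons
  drop_step <- function(name, flag) {
    flag[is.na(flag)] <- FALSE
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, n_removed = sum(flag), n_remaining = sum(!flag))
    keep[!flag, , drop = FALSE]
  }

  keep <- drop_step("prebaseline_emigration",
                    keep$emigration_age < baseline_age)
  keep <- drop_step("prebaseline_death", keep$death_age < baseline_age)
  keep <- drop_step("missing_education", is.na(keep$education))
  keep <- drop_step("missing_parent",
                    is.na(keep$mother_id) | is.na(keep$father_id) |
                      !(keep$mother_id %in% parents$id) |
                      !(keep$father_id %in% parents$id))

  dead_before <- function(th) {
    d <- parents$death_age
    early <- !is.na(d) & d < th
    early_ids <- parents$id[early]
    keep$mother_id %in% early_ids | keep$father_id %in% early_ids
  }
  keep <- drop_step(
    "parent_death_before_threshold",
    if (is.null(parental_age_threshold)) rep(FALSE, nrow(keep))
    else dead_before(parental_age_threshold))

  if (exclude_alive_parents) {
    alive_ids <- parents$id[parents$alive_at_admin == 1L]
    keep <- drop_step("parent_alive_at_admin",
                      keep$mother_id %in% alive_ids |
                        keep$father_id %in% alive_ids)
  }

  over_ids <- parents$id[!is.na(parents$attained_age) &
                           parents$attained_age > parental_age_max]
  keep <- drop_step("parent_attained_over_max",
                    keep$mother_id %in% over_ids |
                      keep$father_id %in% over_ids)

  ledger <- rbind(
    data.frame(step = "initial", n_removed = 0L, n_remaining = nrow(persons)),
    do.call(rbind, steps)
  )
  class(ledger) <- c("exclusion_ledger", "data.frame")

  parents_kept <- parents[parents$id %in% c(keep$mother_id, keep$father_id), ,
                          drop = FALSE]
  list(persons = keep, parents = parents_kept, ledger = ledger)
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Exclusion cascade\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
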