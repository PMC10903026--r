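test_that("follow-up rows are constructed directly from the histories", {
  tc <- toy_cohort()
  expo <- build_exposure(tc$persons, tc$parents)
  b <- c(60, 73, 80, 90)  # fixed quartile boundaries for 4 subjects

  ## person 1: I21 admission at 45, death at 60
  ds9 <- build_outcome_dataset(tc$persons, tc$parents, tc$diagnoses, expo,
                               9, quartile_boundaries = b[2:4] + 0.5)
  r1 <- ds9[ds9$person_id == 1, ]
  expect_equal(r1$time, 6)
  expect_equal(as.character(r1$status), "event")

  dsm <- build_outcome_dataset(tc$persons, tc$parents, tc$diagnoses, expo,
                               "all_cause_death",
                               quartile_boundaries = b[2:4] + 0.5)
  r1m <- dsm[dsm$person_id == 1, ]
  expect_equal(r1m$time, 21)
  expect_equal(as.character(r1m$status), "event")

  ## person 2: nothing happens -> censored at administrative end
  expect_equal(dsm$time[dsm$person_id == 2], 66.9 - 39)
  expect_equal(as.character(dsm$status[dsm$person_id == 2]), "censored")

  ## person 3: I50 at 55 but emigrated at 50 -> competing at time 11
  r3 <- ds9[ds9$person_id == 3, ]
  expect_equal(r3$time, 11)
  expect_equal(as.character(r3$status), "competing")
  ## for mortality, emigration merely censors
  expect_equal(as.character(dsm$status[dsm$person_id == 3]), "censored")

  ## death is a competing event for chapters without an admission
  ds11 <- build_outcome_dataset(tc$persons, tc$parents, tc$diagnoses, expo,
                                11, quartile_boundaries = b[2:4] + 0.5)
  expect_equal(as.character(ds11$status[ds11$person_id == 1]), "competing")
  expect_equal(ds11$time[ds11$person_id == 1], 21)

  ## exposure is centred and in decades
  expect_equal(ds9$exposure_decades,
               (expo$exposure - mean(expo$exposure)) / 10)
})

test_that("a diagnosis before entry is a data error", {
  tc <- toy_cohort()
  expo <- build_exposure(tc$persons, tc$parents)
  tc$diagnoses$age_at_admission[1] <- 30
  expect_error(
    build_outcome_dataset(tc$persons, tc$parents, tc$diagnoses, expo, 9,
                          quartile_boundaries = c(70, 80, 88)),
    "before entry")
})

test_that("chapter event counts equal a brute-force enumeration", {
  coh <- generate_cohort(generator_config(n_persons = 600, seed = 31))
  ex <- apply_exclusions(coh$persons, coh$parents)
  expo <- build_exposure(ex$persons, ex$parents)
  dd <- coh$diagnoses
  chap <- map_icd_chapter(dd$code_system, dd$code)
  total_pkg <- 0
  total_oracle <- 0
  for (ch in icd_chapters()$chapter) {
    ds <- build_outcome_dataset(ex$persons, ex$parents, coh$diagnoses,
                                expo, ch)
    total_pkg <- total_pkg + sum(ds$status == "event")
    ## independent enumeration: any admission in the chapter inside the
    ## person's own follow-up window
    cnt <- 0
    for (i in seq_len(nrow(ex$persons))) {
      p <- ex$persons[i, ]
      end <- min(p$death_age, p$emigration_age, 66.9, na.rm = TRUE)
      ages <- dd$age_at_admission[dd$person_id == p$id & chap == ch]
      ## a terminal admission at the death age still counts
      if (any(ages <= end)) cnt <- cnt + 1
    }
    total_oracle <- total_oracle + cnt
    expect_equal(sum(ds$status == "event"), cnt)
    ## one row per eligible person
    expect_equal(nrow(ds), nrow(ex$persons))
    expect_false(anyDuplicated(ds$person_id) > 0)
  }
  expect_equal(total_pkg, total_oracle)
})

test_that("direct-mode event fractions fall across exposure quartiles", {
  ds <- make_dataset(clean_config(
    n_persons = 20000, mode = "direct", seed = 12,
    theta_mortality = log(0.7),
    theta_chapter = c("9" = log(0.75)),
    offspring_base_hazards = c(all_cause_death = 0.006, "9" = 0.007)))
  frac <- tapply(ds$status == "event", ds$quartile, mean)
  expect_true(all(diff(frac) < 0))
})
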