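test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_persons = 400, seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$persons, b$persons)
  expect_identical(a$parents, b$parents)
  expect_identical(a$diagnoses, b$diagnoses)
})

test_that("parental death ages follow the closed-form Gompertz law when
          frailty and the Makeham term are switched off", {
  ## direct mode disables administrative censoring, so death ages are
  ## fully observed; compare empirical quantiles to the inverse CDF
  cfg <- clean_config(n_persons = 20000, mode = "direct", seed = 8,
                      frailty_shape = Inf, makeham_c = 0,
                      theta_chapter = c("9" = 0),
                      offspring_base_hazards = c(all_cause_death = 0.003))
  par <- generate_parents(cfg)
  a <- cfg$gompertz_a; b <- cfg$gompertz_b
  p <- seq(0.1, 0.9, 0.1)
  q_theory <- log1p((b / a) * (-log(1 - p))) / b
  q_emp <- unname(quantile(par$death_age, p))
  expect_lt(max(abs(q_emp - q_theory)), 0.35)
})

test_that("frailty mixing decelerates the population hazard as the
          closed-form gamma-frailty identity predicts", {
  ## marginal survival under Gamma(k, mean 1) frailty: (1 + H0(x)/k)^-k
  cfg <- clean_config(n_persons = 30000, mode = "direct", seed = 15,
                      frailty_shape = 2, makeham_c = 0,
                      theta_chapter = c("9" = 0),
                      offspring_base_hazards = c(all_cause_death = 0.003))
  par <- generate_parents(cfg)
  a <- cfg$gompertz_a; b <- cfg$gompertz_b; k <- 2
  H0 <- function(x) a / b * expm1(b * x)
  S_pop <- function(x) (1 + H0(x) / k)^(-k)
  xs <- c(60, 70, 80, 90, 100)
  S_emp <- vapply(xs, function(x) mean(par$death_age > x), numeric(1))
  expect_lt(max(abs(S_emp - S_pop(xs))), 0.02)
  ## deceleration: population hazard falls below the frailty-free hazard
  h0 <- function(x) a * exp(b * x)
  h_pop <- function(x) h0(x) / (1 + H0(x) / k)
  expect_true(all(h_pop(xs) < h0(xs)))
  S_ind <- function(x) exp(-H0(x))
  expect_true(all(S_pop(c(90, 100)) > S_ind(c(90, 100))))
})

test_that("the default calibration reproduces the registry features", {
  cfg <- generator_config(n_persons = 30000, seed = 5)
  coh <- generate_cohort(cfg)
  par <- coh$parents
  ## about a tenth of parents alive at the administrative cut-off, none
  ## of them younger than 80
  expect_gt(mean(par$alive_at_admin), 0.07)
  expect_lt(mean(par$alive_at_admin), 0.15)
  expect_gte(min(par$attained_age[par$alive_at_admin == 1]), 80)
  ## premature deaths and overage records exist to exercise exclusions
  expect_gt(sum(!is.na(par$death_age) & par$death_age < 55), 0)
  expect_gt(sum(par$attained_age > 115), 0)
  ## quartile cut points of the analysis exposure land near the reported
  ## boundaries 76.5 / 82 / 86.9
  ex <- apply_exclusions(coh$persons, coh$parents)
  expo <- build_exposure(ex$persons, ex$parents)
  cuts <- unname(quantile(expo$exposure, c(0.25, 0.5, 0.75)))
  expect_lt(max(abs(cuts - c(76.5, 82, 86.9))), 1.5)
})

test_that("cohort structure invariants hold", {
  coh <- generate_cohort(generator_config(n_persons = 2000, seed = 3))
  p <- coh$persons
  linked <- !is.na(p$mother_id) & !is.na(p$father_id)
  expect_true(all(p$mother_id[linked] != p$father_id[linked]))
  expect_true(all(na.omit(c(p$mother_id, p$father_id)) %in% coh$parents$id))
  ## no diagnosis after death or emigration
  d <- coh$diagnoses
  i <- match(d$person_id, p$id)
  expect_true(all(d$age_at_admission <= p$death_age[i] |
                    is.na(p$death_age[i])))
  expect_true(all(d$age_at_admission < p$emigration_age[i] |
                    is.na(p$emigration_age[i])))
  ## pre-ICD-10 admissions carry ICD-9 codes and map to the same chapters
  early <- d$age_at_admission < coh$truth$icd9_until_age
  expect_true(all(d$code_system[early] == "ICD9"))
  expect_true(all(d$code_system[!early] == "ICD10"))
  expect_true(all(!is.na(map_icd_chapter(d$code_system, d$code))))
})

test_that("null mode encodes no effect and direct mode refuses alive parents", {
  cfg <- generator_config(n_persons = 10, mode = "null", seed = 1,
                          theta_mortality = log(0.5))
  expect_identical(cfg$theta_mortality, 0)
  expect_true(all(cfg$theta_chapter == 0))

  cfg_f <- generator_config(n_persons = 3000, mode = "frailty", seed = 2)
  par_f <- generate_parents(cfg_f)
  cfg_d <- generator_config(n_persons = 3000, mode = "direct", seed = 2)
  expect_gt(sum(par_f$alive_at_admin), 0)
  expect_error(generate_offspring(cfg_d, par_f), "alive")
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(education_probs = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(generator_config(theta_mortality = Inf), "finite")
  expect_error(generator_config(frailty_shape = 0), "frailty_shape")
  expect_error(generator_config(gompertz_a = -1), "non-negative")
  expect_error(generator_config(n_persons = 0), "n_persons")
})

test_that("frailty mode induces a positive association between parental
          attained age and offspring death age", {
  cfg <- clean_config(n_persons = 15000, mode = "frailty", seed = 1,
                      frailty_shape = 2, frailty_power = 1.5,
                      theta_chapter = c("9" = log(0.8)),
                      offspring_base_hazards = c(all_cause_death = 0.05,
                                                 "9" = 0.00688),
                      emigration_rate = 0)
  coh <- generate_cohort(cfg)
  p <- coh$persons
  att <- coh$parents$attained_age
  names(att) <- coh$parents$id
  A <- (att[as.character(p$mother_id)] + att[as.character(p$father_id)]) / 2
  died <- !is.na(p$death_age)
  expect_gt(cor(A[died], p$death_age[died], method = "spearman"), 0.05)
})

test_that("cohorts round-trip losslessly through the delimited files", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  coh <- generate_cohort(generator_config(n_persons = 300, seed = 21))
  write_cohort(coh, dir1)
  back <- read_cohort(dir1)
  expect_equal(back$persons, coh$persons, ignore_attr = TRUE)
  expect_equal(back$diagnoses, coh$diagnoses, ignore_attr = TRUE)
  expect_equal(back$truth$theta_chapter, coh$truth$theta_chapter)
  expect_equal(back$truth$offspring_base_hazards,
               coh$truth$offspring_base_hazards)
  ## write -> read -> write is byte-identical
  write_cohort(back, dir2)
  for (f in c("persons.csv", "parents.csv", "diagnoses.csv")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
})

test_that("an empty cohort writes valid headers only", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(generator_config(n_persons = 50, seed = 2))
  empty <- coh
  empty$persons <- coh$persons[0, ]
  empty$parents <- coh$parents[0, ]
  empty$diagnoses <- coh$diagnoses[0, ]
  write_cohort(empty, dir)
  lines <- readLines(file.path(dir, "persons.csv"))
  expect_length(lines, 1L)
  expect_match(lines, "^id,sex,birth_year,education")
})
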