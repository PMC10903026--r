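test_that("the toy partial likelihood is maximized where brute force says", {
  d <- data.frame(time = c(1, 2, 3, 4), status = c(1, 1, 1, 0),
                  x = c(1, 0, 1, 0))
  fit <- cox_fit(d, covariate = "x")
  beta_oracle <- oracle_cox_beta(d$time, d$status, d$x)
  expect_equal(unname(fit$beta), beta_oracle, tolerance = 1e-6)
  expect_equal(unname(fit$hr), exp(unname(fit$beta)), tolerance = 1e-12)
  expect_equal(unname(fit$ci95["low", ]),
               exp(unname(fit$beta) - 1.959964 * unname(fit$se)),
               tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("cox_fit equals the grid/enumeration oracle on fuzzed tiny data", {
  set.seed(11)
  done <- 0
  while (done < 25) {
    n <- sample(4:12, 1)
    d <- data.frame(time = runif(n, 0.1, 10), status = rbinom(n, 1, 0.6),
                    x = rnorm(n))
    if (sum(d$status) < 2 || var(d$x) == 0) next
    beta_oracle <- oracle_cox_beta(d$time, d$status, d$x)
    if (abs(beta_oracle) > 6) next  # near-separation; oracle hits bounds
    fit <- cox_fit(d, covariate = "x")
    expect_equal(unname(fit$beta), beta_oracle, tolerance = 1e-6)
    done <- done + 1
  }
})

test_that("cox_fit agrees with the reference survival implementation", {
  library(survival)
  set.seed(42)
  worst <- 0
  for (i in 1:50) {
    n <- sample(40:160, 1)
    d <- data.frame(
      ## rounding induces ties, exercising the Efron correction
      time = round(rexp(n), sample(c(1, 3), 1)) + 0.01,
      status = rbinom(n, 1, 0.6),
      x = rnorm(n),
      s = sample(letters[1:3], n, TRUE))
    if (sum(d$status) < 5) next
    if (i %% 2 == 0) {
      fit <- cox_fit(d, covariate = "x", strata = "s")
      ref <- coxph(Surv(time, status) ~ x + strata(s), d, ties = "efron")
    } else {
      fit <- cox_fit(d, covariate = "x")
      ref <- coxph(Surv(time, status) ~ x, d, ties = "efron")
    }
    worst <- max(worst,
                 abs(unname(fit$beta) - unname(coef(ref))),
                 abs(unname(fit$se) - sqrt(vcov(ref)[1, 1])),
                 abs(fit$loglik - ref$loglik[2]))
  }
  expect_lt(worst, 1e-6)
})

test_that("a stratified fit on a rounded-to-days cohort matches coxph", {
  library(survival)
  ds <- make_dataset(clean_config(
    n_persons = 4000, mode = "direct", seed = 77,
    theta_chapter = c("9" = log(0.8)),
    offspring_base_hazards = c(all_cause_death = 0.01, "9" = 0.007),
    round_ages_to_days = TRUE))
  strata_vars <- c("sex", "education")
  fit <- cox_fit(ds, strata = strata_vars)
  ref <- coxph(Surv(time, status == "event") ~ exposure_decades +
                 strata(sex, education), data = ds, ties = "efron")
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), sqrt(vcov(ref)[1, 1]), tolerance = 1e-6)
})

test_that("estimates are invariant to affine recentering of the covariate", {
  set.seed(5)
  n <- 80
  d <- data.frame(time = rexp(n) + 0.01, status = rbinom(n, 1, 0.6),
                  x = rnorm(n, 50, 10))
  f1 <- cox_fit(d, covariate = "x")
  d$x <- d$x - 123.4
  f2 <- cox_fit(d, covariate = "x")
  expect_equal(unname(f1$beta), unname(f2$beta), tolerance = 1e-8)
  expect_equal(unname(f1$se), unname(f2$se), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(time = 1:6, status = c(1, 1, 0, 1, 0, 1),
                  x = c(1, 1, 1, 2, 2, 2),
                  s = c("a", "a", "a", "b", "b", "b"))
  ## covariate constant within every stratum -> flat likelihood
  expect_error(cox_fit(d, covariate = "x", strata = "s"), "degenerate")
  d0 <- data.frame(time = 1:4, status = 0, x = rnorm(4))
  expect_error(cox_fit(d0, covariate = "x"), "no events")
})
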