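# build a bare outcome-like table with fixed event counts per cell
impact_table <- function(cells) {
  ## cells: data.frame(quartile, sex, education, n, events)
  do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    with(cells[i, ], data.frame(
      status = rep(c("event", "censored"), c(events, n - events)),
      quartile = quartile, sex = sex, education = education))
  }))
}

test_that("exchangeable groups produce a near-zero avoided fraction", {
  set.seed(2)
  n <- 4000
  d <- data.frame(status = sample(c("event", "censored"), n, TRUE,
                                  prob = c(0.15, 0.85)),
                  quartile = sample(paste0("Q", 1:4), n, TRUE),
                  sex = sample(c("M", "F"), n, TRUE),
                  education = sample(1:3, n, TRUE))
  imp <- estimate_impact(d, n_resamples = 100, seed = 4)
  ## under exchangeability the avoided count is mean-zero with variance
  ## from the cell event draws plus the reference-rate estimation error
  p <- mean(d$status == "event")
  s_lab <- paste(d$sex, d$education)
  var_av <- 0
  for (s in unique(s_lab)) {
    m_s <- sum(s_lab == s & d$quartile != "Q4")
    n4 <- sum(s_lab == s & d$quartile == "Q4")
    var_av <- var_av + m_s * p * (1 - p) + m_s^2 * p * (1 - p) / n4
  }
  se_frac <- sqrt(var_av) / imp$observed_events
  expect_lt(abs(imp$avoided_fraction), 3 * se_frac)
})

test_that("two equal unstratified groups reproduce the analytic 1/3", {
  d <- impact_table(data.frame(
    quartile = c("Q1", "Q4"), sex = "M", education = 1L,
    n = 1000, events = c(200, 100)))
  imp <- estimate_impact(d, n_resamples = 200, seed = 1)
  ## counterfactual = 100 + 1000 * 0.1 in expectation -> avoided/observed = 1/3
  expect_equal(imp$observed_events, 300)
  expect_equal(imp$avoided_fraction, 1 / 3, tolerance = 0.03)
  plug <- oracle_impact_plugin(d)
  expect_equal(plug$avoided_fraction, 1 / 3, tolerance = 1e-12)
})

test_that("the stratified estimator matches the plug-in expectation", {
  cells <- expand.grid(quartile = paste0("Q", 1:4), sex = c("M", "F"),
                       education = 1:3)
  set.seed(8)
  cells$n <- sample(300:500, nrow(cells), TRUE)
  ## education-dependent event probabilities, lower in Q4
  p <- with(cells, 0.05 * education + ifelse(quartile == "Q4", 0, 0.05))
  cells$events <- round(cells$n * p)
  d <- impact_table(cells)
  imp <- estimate_impact(d, n_resamples = 400, seed = 3)
  plug <- oracle_impact_plugin(d)
  expect_equal(imp$counterfactual_events, plug$counterfactual,
               tolerance = 0.005)
  ## invariants of the estimate object
  ps <- imp$per_stratum
  expect_equal(imp$counterfactual_events,
               sum(d$quartile == "Q4" & d$status == "event") +
                 sum(ps$expected), tolerance = 1e-9)
  expect_equal(sum(ps$m) + sum(d$quartile == "Q4"), nrow(d))
})

test_that("reference covering all quartiles reproduces observed counts", {
  d <- impact_table(data.frame(
    quartile = rep(paste0("Q", 1:4), 2), sex = rep(c("M", "F"), each = 4),
    education = 1L, n = 100, events = c(20, 15, 10, 5, 18, 14, 9, 6)))
  imp <- estimate_impact(d, reference = paste0("Q", 1:4),
                         n_resamples = 5, seed = 9)
  expect_equal(imp$avoided, 0)
  expect_equal(imp$counterfactual_events, imp$observed_events)
})

test_that("resampling is reproducible and fails on empty reference cells", {
  d <- impact_table(data.frame(
    quartile = c("Q1", "Q4"), sex = "M", education = 1L,
    n = 50, events = c(10, 5)))
  i1 <- estimate_impact(d, n_resamples = 20, seed = 7)
  i2 <- estimate_impact(d, n_resamples = 20, seed = 7)
  expect_identical(i1$counterfactual_events, i2$counterfactual_events)

  d_bad <- impact_table(data.frame(
    quartile = c("Q1", "Q4", "Q2"), sex = c("M", "M", "F"),
    education = 1L, n = 50, events = 5))
  expect_error(estimate_impact(d_bad), "empty reference cell")
})

test_that("impact_summary pools hospitalization chapters by summed counts", {
  mk <- function(outcome, obs, cf) {
    structure(list(outcome = outcome, observed_events = obs,
                   counterfactual_events = cf, avoided = obs - cf,
                   avoided_fraction = (obs - cf) / obs, n_resamples = 20,
                   per_stratum = NULL), class = "impact_estimate")
  }
  ## two chapters with avoided 100/1000 and 0/1000 -> pooled 5%
  s <- impact_summary(list(mk("9", 1000, 900), mk("5", 1000, 1000)),
                      expected_outcomes = c("9", "5"))
  pooled <- s[s$outcome == "all_hospitalizations", ]
  expect_equal(pooled$avoided_fraction, 0.05)
  expect_equal(pooled$avoided_pct, 5)
  ## a single outcome summarizes to itself
  s1 <- impact_summary(list(mk("all_cause_death", 800, 600)),
                       expected_outcomes = "all_cause_death")
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$avoided_fraction, 0.25)
  ## missing outcomes are warned about
  expect_warning(
    impact_summary(list(mk("9", 10, 9)),
                   expected_outcomes = c("9", "5")), "missing outcome")
})
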