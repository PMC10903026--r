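# parage

Survival analysis of midlife morbidity and mortality by **parental
attained age** — a parent's age at death or, if still alive at the
administrative cut-off for mortality data, their age on that date.  The
mean of the two parents' attained ages serves as a readily available
proxy for the offspring's *biological age*: people whose parents lived
long tend to age more slowly themselves, and the package quantifies what
that inherited heterogeneity in aging means for death and first-time
hospitalization between ages 39 and 67 in a single-year birth cohort.

The package is aimed at epidemiologists and biostatisticians working with
two-generation registry data (or, as register extracts are rarely
shareable, with synthetic stand-ins for them).  It provides:

* **A synthetic registry-cohort generator** — a two-generation cohort
  with parental lifespans from a shared gamma-frailty Gompertz–Makeham
  model, `h(x | Z) = Z·a·e^{bx} + c`, `Z ~ Gamma(k, mean 1)` per family;
  offspring death, emigration, and first admissions in the ten most
  common ICD-10 chapters, with known ground-truth effect sizes
  (`direct`, `frailty`, and `null` modes).
* **A cohort builder** — the exclusion cascade with a conserving ledger,
  attained-age exposure construction (mean / maternal / paternal),
  quartile categorization, ICD-9/ICD-10 chapter mapping, and per-outcome
  competing-risks survival datasets.
* **A self-contained survival core** — Nelson–Aalen cumulative hazards,
  stratified Cox regression maximizing the partial likelihood
  `∑_s ∑_{i∈D_s} [β'x_i − log ∑_{j∈R_s(t_i)} e^{β'x_j}]` by
  Newton–Raphson with the Efron tie correction, and the k-sample
  log-rank test with hypergeometric variance.  Hazard ratios are per
  decade of mean parental attained age.
* **Onset detection** — the recursive truncated log-rank procedure: test
  the full follow-up at `p < 0.001`, then repeatedly truncate one year
  earlier until the first non-significant test; the last significant
  truncation age is the onset of the risk difference.
* **A counterfactual impact estimator** — within sex × education strata,
  each non-reference quartile cell of size *m* is replaced by *m* draws
  (with replacement) from the same stratum's longest-lived quartile, and
  the averaged resampled event count is compared with the observed one
  to yield the avoided fraction of deaths or hospitalizations.

## Worked example

```r
library(parage)

cfg     <- generator_config(n_persons = 20000, mode = "direct", seed = 7)
cohort  <- generate_cohort(cfg)
ex      <- apply_exclusions(cohort$persons, cohort$parents)
ex$ledger
#> Exclusion cascade
#>                           step n_removed n_remaining
#>                        initial         0       20000
#>         prebaseline_emigration        80       19920
#>              prebaseline_death        80       19840
#>              missing_education       200       19640
#>                 missing_parent       160       19480
#>  parent_death_before_threshold      2169       17311
#>       parent_attained_over_max        17       17294

exposures <- build_exposure(ex$persons, ex$parents)
ds <- build_outcome_dataset(ex$persons, ex$parents, cohort$diagnoses,
                            exposures, 9)        # circulatory system
fit <- cox_fit(ds, strata = c("sex", "education",
                              "mother_birthyear_quartile",
                              "father_birthyear_quartile"))
fit
#> Cox proportional-hazards fit (Efron ties)
#>   n = 17294, events = 2753, strata = 96, iterations = 3
#>                     beta      se     HR ci_low ci_high      p
#> exposure_decades -0.2355 0.02411 0.7902 0.7537  0.8284 <2e-16
```

The generating truth for chapter 9 was a hazard ratio of 0.80 per decade
of mean parental attained age; the stratified fit recovers 0.79 with a
95% CI of 0.75–0.83.  The onset procedure and the counterfactual
estimator read off when the quartile curves separate and how much of the
burden the exposure accounts for:

```r
find_onset(ds)
#> Onset of risk differences (recursive truncated log-rank)
#>   outcome: 9
#>   alpha = 0.001, tests run = 26
#>   onset age: 42 years

estimate_impact(ds, n_resamples = 20, seed = 7)
#> Counterfactual impact estimate
#>   outcome: 9
#>   observed events: 2753
#>   counterfactual events: 2307.9
#>   avoided: 445.1 (16.2% of observed), 20 resamples
```

`run_pipeline()` chains all stages for every outcome and writes the fit,
curve, onset, and impact artifacts plus a manifest;
`scripts/pipeline.R` exposes the same stages as shell subcommands
(`simulate`, `build`, `fit`, `curves`, `onset`, `impact`, `report`).

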