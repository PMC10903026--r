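---
title: "Parental attained age as a proxy for biological age: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parental attained age as a proxy for biological age: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Aging advances at different rates in different people, and a biological
age that runs ahead of chronological age raises the risk of disease and
death.  Direct biomarkers of biological age are expensive and themselves
entangled with the disease processes they are meant to predict.  Lifespans,
however, are inherited: parents' ages at death predict their children's
mortality and morbidity in a graded, approximately log-linear way.  This
package operationalizes that observation for two-generation registry
cohorts: the *mean parental attained age* — each parent contributing their
age at death, or their age at the administrative cut-off if still alive —
is used as the exposure, and offspring all-cause mortality and first-time
hospitalization in the ten most common ICD-10 chapters are the outcomes,
followed from exact age 39 to administrative end of follow-up at 66.9
years.

Four questions structure the analysis, and one package module answers
each: how strongly each outcome depends on the exposure (stratified Cox
regression, hazard ratios per decade); from which age the exposure
quartiles separate (recursive truncated log-rank testing); whether the
dependence is graded across quartiles (Nelson–Aalen curves and quartile
contrasts); and how much of the total burden the exposure accounts for
(counterfactual resampling).

Because person-level register extracts cannot be shared, everything is
exercised on synthetic cohorts with known ground truth.  The generator is
a first-class, tested component, not a fixture: recovering its encoded
parameters through the full pipeline is the package's primary
correctness argument.

## The synthetic cohort generator

### Parents

Each of the `n` index persons draws a family frailty
$Z \sim \Gamma(k, \text{mean } 1)$ (variance $1/k$; $k = \infty$ switches
heterogeneity off).  Both parents' lifespans are sampled by inverting the
Gompertz–Makeham cumulative hazard conditional on $Z$:

$$h(x \mid Z) = Z\,a\,e^{bx} + c .$$

The Makeham term $c$ generates age-independent (premature) mortality and
is the dial controlling how many parents die before the attained-age
threshold of 55; the shared $Z$ makes the two lifespans within a couple
positively dependent and transmits risk to the offspring in frailty mode.
An optional Gaussian copula parameter adds within-couple dependence
*beyond* the shared frailty; since no empirical value for that residual
correlation is established, it defaults to 0 and the shared frailty is
the only built-in couple dependence.

Parents' ages at the index birth are truncated normals (mothers
mean 26.5, SD 6, range 14–45; fathers 29.5, SD 6.5, range 16–60).  A
parent's administrative censor age is the cohort's age at the parental
mortality cut-off (68 years) plus their age at the index birth, so the
youngest possible alive parent is 82 — consistent with the registry
feature that no alive parent is younger than 80.  Defaults
($a = 1.35\times10^{-5}$, $b = 0.105$, $c = 3\times10^{-4}$, $k = 6$)
were calibrated once so that (i) the quartile cut points of the mean
parental attained age land near 76.5 / 82 / 86.9 years and (ii) roughly
a tenth of parents are alive at the cut-off; both are features of the
registry population the generator emulates.  Rare corrupted death records
above age 115 (a register artifact of unrecorded emigration) are injected
at rate $3\times10^{-4}$ to exercise the exclusion cascade.

### Offspring

Given the exposure $A$ (mean parental attained age), every outcome $j$
(death, ten chapters) has a constant baseline hazard over the 27.9-year
window, multiplied according to the generating mode:

* **direct** — $\lambda_j = \text{base}_j \exp\{\theta_j (A - \bar A)/10\}$,
  so $e^{\theta_j}$ is the true cause-specific hazard ratio per decade.
  Administrative censoring of parents is disabled here so the exposure is
  exact.  The default $\theta$'s encode an all-cause mortality HR of 0.78
  and chapter HRs between 0.80 and 0.93 per decade, with baseline rates
  giving ~9% cumulative mortality and chapter first-event fractions
  between ~4% and ~17% — the orders of magnitude of the emulated cohort.
* **frailty** — $\lambda_j = \text{base}_j\, Z^{w}/E[Z^w]$: the family
  frailty acts multiplicatively on offspring hazards with no directly
  encoded exposure effect; associations arise purely through inheritance.
* **null** — all effects off; every downstream estimate must be null.

Constant baselines are a deliberate simplification: the emulated
cumulative hazards are near-linear in this age window, constants make
inversion sampling exact, and parameter-recovery tests need a correct
proportional-hazards truth, not a realistic age profile.  An optional
change-point (`effect_onset_age`) switches the exposure effect on only
beyond a given age, giving the onset-detection module a known truth to
localize.  Event ages are continuous to machine precision; an optional
flag rounds them to whole days to create ties and exercise the Efron
correction.  Emigration is exponential censoring; education is
multinomial with the emulated cohort's level fractions; a diagnosis at
the same age as death is recorded before the death, so a terminal
admission counts for its chapter *and* for mortality.

One seed drives fixed stream offsets (parents, demographics, event times,
emigration, record artifacts), so each sub-stage is independently
reproducible.

### What the generator does not emulate

Real registers have calendar-time structure (month-of-birth staggering,
ICD-9→ICD-10 code-level conversion, repeat admissions, cause-specific
parental mortality), age-increasing offspring baselines, and
socially structured exposure–confounder correlation.  Passing recovery
tests on synthetic data therefore demonstrates the *estimators'*
correctness under the stated model, not robustness of the scientific
conclusion to confounding in real data.

## Cohort building

The exclusion cascade applies, in the narrative order: pre-baseline
emigration, pre-baseline death, missing education, missing either parent
link, any parent dead before 55 (configurable; `NULL` for the full-range
sensitivity analysis), optionally any parent alive at the cut-off, and
any parent recorded above 115.  The ledger records removed/remaining
counts per step and must conserve totals; only the final n and
conservation are contractual, since the step order affects per-step
counts but not the final sample.

Quartile intervals are lower-open/upper-closed with Q1 closed at its
minimum.  The emulated cohort's printed boundaries touch (76.5 ends Q1
and begins Q2), so a convention is required; placing boundary values in
the lower quartile is the one fixed here.  Empirical boundaries are
type-7 sample quartiles, which keeps group sizes within one of each other
for continuous exposures.

For hospitalization outcomes the analysis is cause-specific: death and
emigration are competing events, coded distinctly (`competing`) but
treated as censoring in fits and tests alike — including inside the
truncated onset tests.  The continuous exposure enters centred at the
sample mean and scaled to decades; centring does not change hazard
ratios and only stabilizes the optimization.

## The survival core

`cox_fit()` maximizes the stratified partial likelihood with the Efron
tie correction (the convention of the standard survival software this
field uses, and the better approximation when event ages are rounded to
days).  Newton–Raphson starts at 0, converges when the score norm falls
below $10^{-9}$ or the relative log-likelihood change below $10^{-12}$,
halves steps on any likelihood decrease, and flags non-convergence after
25 iterations.  Strata are the cross-classification of the selected
variables (sex, education, maternal and paternal birth-year quartiles).
Entering the two birth-year quartiles "separately" could also be read as
two marginally stratified models; cross-classification is the
conservative reading that nests the alternative, and the marginal
variants remain available by passing fewer strata columns.  Degenerate
inputs (no events, or a covariate constant within every risk set) raise
errors rather than returning spurious estimates.  Wald p-values
(`beta/se` against the standard normal) match standard survival-package
reporting.

`logrank_k()` accumulates observed-minus-expected event counts per group
with the hypergeometric variance–covariance at each distinct event time,
dropping one group to invert the covariance (with an SVD pseudo-inverse
fallback for near-singular risk patterns).  `nelson_aalen()` accumulates
$d_i/n_i$ increments.  All three are validated against independent
oracles: brute-force risk-set enumeration, hand tabulation, closed-form
hazards, and the reference `survival` implementation (which is used only
as a cross-check, never as the computational path).

## Onset detection

The recursive procedure tests the complete follow-up first; while
significant at $\alpha = 0.001$, follow-up is administratively censored
one grid year earlier and retested.  The onset is the last significant
truncation age; if the first test fails there is no onset.  Truncation
censors at the cut rather than deleting subjects, matching the reading
of "follow-up until" a calendar year-end, and calendar year-ends are
collapsed to integer ages since everyone shares a birth year (the first
grid age labels the full-follow-up test; the distortion is below one
year).  Each test is recomputed from scratch — rerunning with a grid
prefix reproduces the trace prefix exactly.  The sequence is deliberately
uncorrected for multiplicity: it is the descriptive localization the
original procedure defines, not an inferential claim, which is also why
the package reports the whole trace.

For the change-point recovery experiment the committed scenario is
n = 50,000, baseline death rate 0.012/year, per-decade HR 0.5 switching
on at age 55.  The design reasoning, fixed before testing: with ~19
years of null follow-up diluting the log-rank variance, three years of
accumulated differential hazard (~1,600 events spread ~3:1 across
quartiles) puts the truncated chi-square far beyond the 0.001 threshold
at age 58, while tests at 55 and below see no signal, so detected onsets
concentrate in 56–58.

## The counterfactual impact estimator

Within each sex × education stratum, every non-reference quartile cell of
size $m$ is replaced by $m$ persons drawn with replacement from the
stratum's reference (longest-lived) quartile; their observed event
indicators — over their own follow-up, so donor censoring is inherited —
are summed, the draw is averaged over 20 resamples (configurable), and
reference subjects keep their observed events.  The avoided fraction
divides by *all* observed events, including the reference quartile's,
matching a population-level "share of deaths avoided" reading.  In
expectation the estimator equals the plug-in
$\sum_{s,q} m_{s,q}\,\hat p_{s,\text{ref}}$; the tests verify convergence
to it at 2,000 resamples and calibration of the Monte-Carlo error at 20.
Expected counts stay fractional internally; rounding to whole cases and
whole percent happens only in the summary table, which also pools
hospitalization chapters by summing observed and counterfactual
first-time events before forming the fraction.  Draws follow one seed in
a documented order (strata sorted lexicographically, then quartiles), so
results are exactly reproducible.  The estimate answers a hypothetical
— "if the association were causal, what would making every family
long-lived change?" — and no causal adjustment beyond the stratification
is attempted.

## Numerical choices and degenerate inputs

* Exposure ties at quartile boundaries go to the lower quartile; values
  outside explicit outer bounds go to the nearest extreme quartile with a
  warning.
* Log-rank covariance is scaled by $(n_t - d_t)/(n_t - 1)$ with the
  $n_t = 1$ term set to zero.
* The Gompertz–Makeham inverse uses the closed form when $c = 0$ and
  otherwise Newton iteration from the closed-form start, which converges
  monotonically because the cumulative hazard is convex and the start
  overshoots.
* Partial-likelihood computations centre the linear predictor within
  stratum; the partial likelihood is invariant to this shift.
* Confidence intervals use $\exp(\beta \pm 1.959964\,\mathrm{se})$.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of a few hundred to 30,000
persons.  The recovery checks use the full 90,000-person scenario (one
cohort per outcome family), the log-rank size check uses 10,000 null
replicates of 500 subjects, the change-point experiment 50 replicates of
50,000, and the null-onset experiment 100 replicates of 4,000.  These
sizes were chosen so each check's Monte-Carlo error is small relative to
its tolerance while the whole suite stays quick on a single CPU.

## Known limitations

Constant offspring baselines and exponential emigration are adequate for
estimator validation but not for forecasting absolute risks; the ICD-9
mapping uses only the printed three-digit category ranges, not a
code-level conversion; calendar dates are collapsed to exact ages; and
the counterfactual estimator presumes a non-empty reference cell in every
stratum — sparse strata should be coarsened before calling it.
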