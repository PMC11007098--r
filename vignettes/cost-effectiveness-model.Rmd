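---
title: "A three-state cost-effectiveness model of adjuvant osimertinib in resected EGFR-mutated NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state cost-effectiveness model of adjuvant osimertinib in resected EGFR-mutated NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osimCEA)
```

## The decision problem

Adjuvant osimertinib, an oral third-generation EGFR tyrosine-kinase
inhibitor given for up to three years after complete resection of stage
IB--IIIA EGFR-mutated non-small cell lung cancer, delays recurrence and
extends overall survival relative to placebo, but at a high acquisition
price. `osimCEA` implements a cohort-level cost-utility model comparing the
two strategies from a U.S. payer perspective: it extrapolates fitted
disease-free survival (DFS) and overall survival (OS) curves over a lifetime
horizon, accrues discounted costs and quality-adjusted life-years (QALYs)
per arm, and summarizes the comparison as an incremental cost-effectiveness
ratio (ICER) judged against a willingness-to-pay (WTP) threshold of
\$150,000/QALY.

## Model structure

Patients occupy one of three mutually exclusive health states: disease-free,
disease recurrence, and death. Time advances in 3-week cycles (21 days,
`21/30.4375` months under the mean-month day count) for 275 cycles, carrying
a cohort entering at age 63 to the average U.S. life expectancy at birth of
78.8 years. Costs and QALYs are discounted at 3% per year and accrued with a
half-cycle correction (the mean of start- and end-of-cycle occupancy).

State occupancy is derived by **curve partition** (partitioned survival):
at each cycle boundary `t`, disease-free occupancy is `S_DFS(t)`, death is
`1 - S_OS(t)` and recurrence is the difference, clipped at zero. The model
uses partition rather than an explicit recurrence-to-death transition matrix
because only marginal DFS and OS curves are identifiable from arm-level
trial reporting; partition reproduces exactly the curves that were fitted.
An explicit state-transition variant (`model_spec(engine = "markov")`), in
which every DFS exit beyond background mortality passes through recurrence
and leaves it at the OS conditional hazard, is provided for structural
sensitivity exploration; it necessarily implies more recurrence person-time
and should be read as a bounding scenario, not the base case.

Background mortality enters as a hazard floor: each cycle's conditional
death probability is the larger of the OS curve's conditional probability
`1 - S(t_k)/S(t_{k-1})` and the age-specific annual probability of an
abridged life table converted to the cycle length via
`1 - (1 - q)^(cycle years)`. The bundled table is a synthetic stand-in,
Gompertz-smoothed to the magnitude of recent U.S. period life tables;
because the cohort never ages past 78.8 years, where the fitted disease
hazards still dominate general-population mortality, the floor almost never
binds and results are insensitive to its exact values.

## Survival inputs

The four base-case curves (time in months) are:

| Endpoint / arm  | Family            | Parameters |
|-----------------|-------------------|------------|
| DFS, osimertinib| log-logistic      | shape 1.63351, scale 112.73457 |
| DFS, placebo    | generalized gamma | mu 2.88767, sigma 1.45261, Q -1.30760 |
| OS, osimertinib | generalized gamma | mu 4.36038, sigma 1.26750, Q -3.13596 |
| OS, placebo     | log-normal        | meanlog 4.83614, sdlog 1.01581 |

Two conventions are deliberate design choices. First, the **time unit is
months**: the implied medians (112.7 for active-arm DFS, `exp(4.83614)`
= 126 for placebo OS) are clinically plausible in months and absurd in
weeks or cycles. Second, the generalized gamma uses the **Prentice
(mu, sigma, Q) parameterization** (the `flexsurv` convention), under which
`Q -> 0` recovers the log-normal and `Q = 1` the Weibull; this is the form
in which fitted triplets are conventionally reported, and the package's
tests verify both nesting limits numerically. As a further check of the
sign convention, the fitted OS curves evaluated at 60 months reproduce the
trial-reported 5-year OS of roughly 88% (osimertinib) and 78% (placebo);
flipping the sign of Q collapses the active-arm OS curve entirely.

```{r curves}
curves <- base_case_survival()
round(vapply(curves, survival_at, numeric(1), t = 60), 3)
round(vapply(curves, median_survival, numeric(1)), 1)
```

## Valuation

Per-year utilities are 0.83 (disease-free), 0.74 (recurrence) and 0
(death). Costs, all in 2023 USD, accrue as follows:

* **Drug acquisition** (active arm): \$566.64 per daily 80 mg dose for
  21 days per cycle while disease-free, capped at the first 52 complete
  cycles (52 x 21 days = 2.99 years, whole-cycle accounting of the 3-year
  treatment limit).
* **Disease-free monitoring**: imaging (\$249.48) + laboratory (\$340.20) +
  physician visit (\$160.20) at weeks 12 and 24 (cycles 4 and 8), then
  every 24 weeks (8 cycles) through year 5, then annually (17 cycles) --
  nearest-cycle rounding of the stated calendar.
* **Subsequent therapy after recurrence** for 67.1% (active) / 66.3%
  (control) of the recurrence state: pemetrexed 500 mg/m^2 plus cisplatin
  75 mg/m^2 induction for the first four cycles after entering the state
  (entrants approximated by disease-free exits), then pemetrexed
  maintenance while the patient remains in the state. Doses use a body
  surface area of 1.82 m^2 and are rounded up to whole 10 mg billing units
  (\$7.51 and \$3.17 per 10 mg). The complementary fraction receives best
  supportive care at \$481.57 per cycle.
* **Recurrence-state management** for all patients: administration
  (\$155.09), laboratory and physician visit every cycle; imaging every
  second cycle.
* **Terminal care**: a one-time \$10,187.64 attached to incident deaths in
  their cycle of death.

Adverse-event costs and disutilities are exactly zero: no severe
treatment-related adverse event exceeded the conventional 5% incidence
screen in the underlying trial, so none meets the usual inclusion rule.
The maintenance stopping rule is the least-assumption reading
(treat-while-in-state); `treatment$maintenance_cap_cycles` caps it for
sensitivity exploration. Accrual is discounted at the end-of-cycle factor
`(1.03)^(-t years)`.

```{r base}
res <- run_base_case()
res
```

## Sensitivity analyses

Because the survival curves are not resampled, both sensitivity analyses
reuse the cohort traces and only re-value them, which keeps 1,000 draws in
the low seconds.

**One-way (tornado).** Every uncertain parameter moves to its low and high
bound with the rest at baseline: explicit bounds where the base case states
them (utilities, unit costs, body surface area), plus/minus 20% for the
subsequent-therapy proportions, and 0--5% for the discount rate (the only
parameter that also changes the discounting itself). Entries are ranked by
absolute ICER spread.

**Probabilistic (PSA).** 1,000 Monte Carlo draws sample unit costs from
gamma, utilities and proportions from beta, and body surface area from a
normal distribution; the discount rate and the survival parameters stay
fixed (no sampling distributions are defined for them -- a deliberate
fidelity choice, so the PSA quantifies economic-parameter uncertainty
only). Each distribution is moment-matched to mean = baseline with the
parameter's range read as its **central 95% interval**,
`sd = (high - low)/(2 * 1.96)`. A single convention across all families was
chosen deliberately: interpreting ranges as 95% intervals is the standard
reading for normal draws, and applying a different, doubly-wide dispersion
(sd equal to the full 20% half-range) only to gamma and beta draws would be
internally inconsistent and noticeably changes the tails -- under the wider
convention a handful of draws per thousand cross the WTP line, whereas
under the consistent convention the probabilistic result is stable.
Beta-moment feasibility is checked when the sampler is constructed, not at
draw time. Draws are reproducible bit-for-bit under a fixed seed.

The **threshold price** searches the daily 80 mg price by bisection until
the recomputed ICER matches the WTP threshold to a relative tolerance of
1e-6 (the incremental cost is linear in the price, but bisection keeps the
search agnostic to that structure).

```{r sens, eval = FALSE}
tor <- one_way_tornado()
head(tor, 3)
psa <- run_psa(n_draws = 1000, seed = 20240328)
ceac(psa, c(0, 150000, 300000, 450000))
threshold_price(wtp = 150000)
```

## Curve reconstruction and refitting

The upstream stage that produced the survival inputs -- digitizing published
Kaplan-Meier figures, regenerating pseudo individual-patient data (IPD),
and refitting parametric families -- is implemented so the whole pipeline is
testable by parameter recovery:

* `digitized_curve()` holds step-curve coordinates plus a numbers-at-risk
  table and validates monotonicity.
* `reconstruct_ipd()` allocates integer event counts at the digitized step
  times and censoring counts within each inter-risk-time interval,
  iterating until the at-risk count at the next table time is matched
  exactly while the recomputed product-limit estimate tracks the digitized
  survival; censoring times are spread uniformly within their interval, and
  events precede censorings at ties. Published reconstruction algorithms
  differ in detail; this interval-allocation variant is documented as the
  package's own, since the downstream use is refitting, not bitwise
  replication of any particular digitization.
* `fit_family()` maximizes the right-censored log-likelihood via
  `flexsurv::flexsurvreg`; the generalized gamma additionally restarts from
  its log-normal (Q = 0) and Weibull (Q = 1) corners and keeps the best
  optimum, which removes the main practical failure mode of that family.
  `select_best()` picks the converged fit with the lowest AIC (default) or
  BIC, breaking ties toward fewer parameters; both criteria are always
  reported. Arms are fitted separately.

`simulate_ipd()` provides ground truth: inverse-transform event times from
any of the seven families, uniform accrual over 24 months with
administrative censoring at the end of follow-up, plus optional exponential
dropout. `digitize()` emulates a graph digitizer (exact at-risk counts,
optional truncated-Gaussian jitter on the survival ordinates,
re-monotonized). The recovery tests regenerate the active-arm DFS
log-logistic from n = 2,000 simulated patients through digitize ->
reconstruct -> refit to within 10% per parameter; the long follow-up used
there (about 30% censoring) is chosen to identify the tail, i.e. it is a
validation condition, not a claim about trial-like follow-up.

## Numerical choices and edge cases

* Conditional per-cycle event probabilities telescope exactly:
  `prod(1 - q_k) = S(K * delta)` to 1e-10, so occupancy never drifts from
  the closed-form curves.
* Exhausted survival (numerically zero at a cycle start) signals a typed
  `exhausted_survival` condition rather than returning `NaN`.
* If the DFS curve exceeds floored OS by more than 0.02 anywhere on the
  grid the engine warns and clips recurrence at zero; smaller violations
  are clipped silently.
* Occupancy conservation holds to 1e-12 over all 275 cycles; death is
  absorbing by construction.
* Dose rounding is always up (ceiling) to the 10 mg billing unit,
  reflecting single-use vials.

## What the tests do and do not show

The synthetic-data generator emulates administrative censoring and
digitization noise, so passing recovery tests demonstrate that the
reconstruction-and-refitting machinery is unbiased at trial-like sample
sizes under independent censoring. They do not validate the clinical
extrapolation itself: real digitized curves carry correlated reading
errors, informative censoring and reporting coarseness that no generator
reproduces. Likewise the cohort model's fidelity is bounded by its inputs
-- arm-level marginal curves, a fixed subsequent-therapy basket (no
re-treatment with osimertinib, no radiotherapy or surgery at recurrence),
age-independent utilities and U.S. unit costs -- and results should be read
as conditional on those published inputs. The recurrence-state cost total
is the quantity most sensitive to accrual interpretation (who receives
best supportive care, imaging frequency, chemotherapy stopping rule); the
package implements the readings stated above and exposes the knobs rather
than tuning them to any external figure.
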