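# osimCEA

Cost-effectiveness analysis of adjuvant osimertinib versus placebo in
completely resected, EGFR-mutated, stage IB–IIIA non-small cell lung cancer,
from a U.S. payer perspective — implemented as a tested, reusable R package
for health-economics practitioners.

## What it computes

A discrete-time cohort model with three mutually exclusive states —
disease-free (DFS), disease recurrence, and death — advances in 3-week
cycles over a 275-cycle lifetime horizon (age 63 to 78.8). State occupancy
is obtained by partitioned survival from fitted parametric curves
(log-logistic, log-normal and Prentice generalized-gamma families, time in
months), with an age-specific life-table floor on the death hazard. Costs
and QALYs accrue per cycle with half-cycle correction and 3% annual
discounting:

* QALYs: `Σ_k (u_DFS·dfs_k + u_rec·rec_k) · Δ_years · (1.03)^(-t_k)`
* Costs: drug acquisition (active arm, 21 days × $566.64/day while
  disease-free, capped at 52 cycles ≈ 3 years), scheduled DFS monitoring,
  pemetrexed–cisplatin induction then pemetrexed maintenance for the
  subsequent-therapy fraction of the recurrence state, best supportive care
  for the rest, per-cycle recurrence management, and one-time terminal care.

The arms combine into the incremental cost-effectiveness ratio
`ICER = ΔCost / ΔQALY`, assessed against a willingness-to-pay threshold of
$150,000/QALY. Around the base case the package provides one-way (tornado)
sensitivity analysis, probabilistic sensitivity analysis (1,000 draws;
gamma for costs, beta for utilities and proportions, normal for body
surface area), cost-effectiveness acceptability curves, and a bisection
search for the drug price at which the ICER equals the threshold.

The upstream evidence pipeline is also included and testable end to end:
reconstruction of pseudo individual-patient data from digitized
Kaplan–Meier curves with numbers-at-risk tables, censored maximum-likelihood
refitting of seven candidate families with AIC/BIC selection, and a
synthetic trial-data generator for parameter-recovery validation.

## Worked example

```r
library(osimCEA)

res <- run_base_case()
res
#> Cost-effectiveness summary (discounted)
#>   control:     cost $     90,372   QALYs   6.72
#>   active:      cost $    626,433   QALYs   8.28
#>   incremental: cost $    536,061   QALYs   1.56
#>   ICER: $343,795.5 per QALY
```

The active strategy gains about 1.56 discounted QALYs at roughly $536k
additional discounted cost, an ICER of ≈ $344k/QALY — well above the
$150,000/QALY threshold, so adjuvant osimertinib is not cost-effective at
its list price under this model.

```r
threshold_price(wtp = 150000)
#> [1] 261.2321
```

The daily 80 mg price would need to fall to about $261 (from $566.64)
for the ICER to reach the threshold.

```r
tor <- one_way_tornado()
head(tor[, c("parameter", "icer_at_low", "icer_at_high", "spread")], 3)
#>          parameter icer_at_low icer_at_high   spread
#> 1      utility_dfs    484040.9     266562.1 217478.7
#> 2 cost_osimertinib    271882.4     415708.6 143826.3
#> 3    discount_rate    270852.9     399289.2 128436.3

psa <- run_psa(n_draws = 1000, seed = 20240328)
mean(psa$delta_cost > 0 & psa$delta_qalys > 0)   # all draws cost more, gain QALYs
#> [1] 1
ceac(psa, 150000)$probability_cost_effective     # none cost-effective at $150k
#> [1] 0
```

The DFS utility, the osimertinib price and the discount rate dominate the
one-way analysis, and no probabilistic draw is cost-effective at the
threshold.

A full report bundle (base case, tornado, PSA samples, CEAC, threshold
price, manifest) can be written with
`run_full_report("out/", n_draws = 1000, seed = 20240328)`.

## Package layout

* `R/survival-models.R` — parametric families, medians, per-cycle hazards
* `R/km-reconstruction.R` — digitized curves → pseudo-IPD, KM estimator
* `R/fitting.R` — censored MLE per family, AIC/BIC selection
* `R/cohort-engine.R` — model spec, discounting, three-state trace
* `R/valuation.R` — cost/QALY accrual, ICER
* `R/sensitivity.R` — tornado, PSA, CEAC, threshold price, plots
* `R/synthetic-data.R` — trial simulator and digitizer emulator
* `R/base-case.R`, `R/parameters.R`, `R/life-table.R` — registry, IO, report
* `vignettes/cost-effectiveness-model.Rmd` — methods and design choices
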