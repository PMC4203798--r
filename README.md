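# tpacea

Cost-effectiveness modelling of intravenous thrombolysis (tPA) within 4.5
hours of acute ischemic stroke, from a Chinese healthcare-payer
perspective.

Thrombolysis with tissue-type plasminogen activator is the standard acute
treatment for ischemic stroke, but the drug is expensive relative to
Chinese healthcare budgets, and evidence on its value for money has come
almost entirely from high-income settings. This package implements, in
full, the decision-analytic model behind a published Chinese evaluation of
that question — so that health economists and methods researchers can
reproduce its base-case results, probe every assumption, and rerun the
analysis under different inputs. All default inputs are the published
registry and trial-derived values; a YAML config can override any of them.

## The model

Two stages:

1. **Decision tree (first 90 days).** Treated patients fall into three
   onset-to-needle windows (0–1.5, 1.5–3, 3–4.5 h) with observed 90-day
   outcome distributions over four modified Rankin Scale states — mRS 0–1,
   mRS 2–3, mRS 4–5, dead — plus symptomatic intracerebral hemorrhage
   (sICH) rates. The untreated arm is reconstructed per window from the
   treated distribution and the treatment-effect odds ratios
   (favorable outcome, death, sICH), splitting the remaining mass between
   mRS 2–3 and mRS 4–5 in the treated arm's proportions.

2. **Markov cohort (annual cycles to 30 years).** Each year survivors face
   recurrent stroke with probability 0.1181 × 1.019^(y−1) (case fatality
   0.2101; survivors move to equal-or-worse disability states), then
   non-stroke death at age-specific rates adjusted by state hazard ratios
   (1 / 1.19 / 2.04) via 1 − (1 − q)^HR. Costs (2011 CNY) and utilities
   accrue per state and are discounted at 3% per year.

Outcomes are discounted quality-adjusted life-years (QALYs) and costs per
arm, their increments ΔE and ΔC, the incremental cost-effectiveness ratio
ICER = ΔC/ΔE, and the net monetary benefit NMB(λ) = λ·ΔE − ΔC at
willingness-to-pay thresholds λ of CNY 35,100 and 105,000 per QALY (1x and
3x 2011 GDP per capita). Uncertainty is handled by one-way (tornado)
sweeps across every input's plausible range and by probabilistic
sensitivity analysis (PSA): 10,000 joint Monte-Carlo draws — beta for
probabilities and utilities, lognormal for costs and ratio-scale inputs —
summarized as a cost-effectiveness plane and an acceptability curve
(CEAC). A patient-level microsimulation that mirrors the cohort engine
event-for-event serves as an independent validation oracle, and a
synthetic patient generator supports parameter-recovery studies.

See `vignettes/model-methods.Rmd` for assumptions, the open design
readings (odds- vs ratio-scale back-transformation, life-table
reconstruction, cycle pro-rating) and numerical conventions.

## Worked example

```r
library(tpacea)

bc <- run_base_case(horizons = c(1, 2, 30), utilities = "base")
bc
#> Base-case cost-effectiveness (discounted, 2011 CNY)
#>
#> # A tibble: 6 × 5
#>   horizon_years arm     qalys cost_cny icer_cny_per_qaly
#>           <dbl> <chr>   <dbl>    <dbl>             <dbl>
#> 1             1 control 0.488   18284.               NA
#> 2             1 tpa     0.537   28138.           201161.
#> 3             2 control 0.933   26934.               NA
#> 4             2 tpa     1.03    36184.            99469.
#> 5            30 control 4.52   113632.               NA
#> 6            30 tpa     4.94   120003.            15253.

glance(bc)
#> # A tibble: 1 × 5
#>   horizon_years delta_cost delta_qaly   icer dominance
#>           <dbl>      <dbl>      <dbl>  <dbl> <chr>
#> 1            30      6372.      0.418 15253. none
```

Reading: treating with tPA costs an extra CNY ~9,250 over two years for a
gain of ~0.093 QALYs (ICER ≈ 99,000 CNY/QALY — just under the 3x-GDP
threshold of 105,000), while over a 30-year lifetime horizon the extra
cost shrinks to ~CNY 6,400 (cheaper long-term care for less-disabled
survivors offsets the drug) and the gain grows to ~0.42 QALYs, an ICER of
~15,000 CNY/QALY — far below even the 1x-GDP threshold. Treatment is
therefore cost-ineffective at one year, borderline at two, and clearly
cost-effective over a lifetime.

Sensitivity analyses:

```r
tor <- run_owsa(load_config())      # tornado, all inputs swept low/high
autoplot(tor)

psa <- run_psa(10000, seed = 1)     # 10,000-draw PSA over the 30-y model
psa
autoplot(psa)                       # CE plane
plot_ceac(psa)                      # acceptability curve
```

A command-line front end wraps the same functions
(`inst/scripts/tpacea`): subcommands `basecase`, `owsa`, `psa`,
`simulate`, `validate`, all writing plain CSV plus a JSON run manifest.

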