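---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpacea)
```

## What the model is

`tpacea` implements a two-stage health-economic model of intravenous
tissue-type plasminogen activator (tPA) given within 4.5 hours of acute
ischemic stroke, from a Chinese healthcare-payer perspective, with every
default input taken from the published evaluation whose results the package
is built to reproduce.

**Stage 1 — decision tree (day 0 to day 90).** Treated patients present in
three onset-to-needle windows (0–1.5, 1.5–3, 3–4.5 h; cohort shares 5.68%,
61.13%, 33.19%). For each window the 90-day outcome distribution over four
modified Rankin Scale (mRS) groups — no disability (mRS 0–1), minor/moderate
disability (mRS 2–3), severe disability (mRS 4–5), dead — and the
symptomatic intracerebral hemorrhage (sICH) rate are observed registry
quantities. The untreated ("control") arm is not observed; it is
reconstructed per window from the treated distribution and the
window-specific treatment-effect odds ratios for mRS 0–1, death and sICH,
with the mass not assigned to mRS 0–1 or death split between mRS 2–3 and
mRS 4–5 in the treated arm's proportions. Windows are then pooled by share.

**Stage 2 — Markov cohort (annual cycles to 30 years).** A cohort aged 63
at the index stroke occupies the four states. Each year, every alive state
faces (in this order):

1. *Recurrent stroke* with probability $r_y = 0.1181 \times 1.019^{\,y-1}$
   (year-on-year escalation). A recurrence is fatal with probability
   0.2101; survivors are reallocated uniformly over the states of equal or
   greater disability (mRS 0–1 → each alive state w.p. 1/3; mRS 2–3 →
   mRS 2–3 or 4–5 w.p. 1/2; mRS 4–5 stays). Function never improves.
2. *Non-stroke death* for the non-recurring mass, at the age-specific rate
   adjusted by the state's hazard ratio (1 / 1.19 / 2.04) via
   $1-(1-q_a)^{\mathrm{HR}}$.

Costs (2011 CNY): one-time hospitalization by discharge state (9,526 /
12,595 / 10,794 for mRS 0–1 / 2–5 / 6), a tPA treatment add-on (10,830) and
an sICH add-on (2,300) in the first cycle; annual post-hospitalization costs
(6,773 mRS 0–1, 10,305 mRS 2–5) thereafter, plus the one-time cost of the
destination state for each recurrent event. Utilities 0.80 / 0.58 / 0.28 / 0
weight life-years into QALYs. Both streams are discounted at 3% per year.
Results are the incremental cost, incremental QALYs, and their ratio
(ICER), judged against willingness-to-pay thresholds of CNY 35,100 and
105,000 per QALY (1x and 3x 2011 GDP per capita).

## Design choices where the published description is open

These were genuinely open readings; each is exposed as an argument so the
alternative can be run, and the default is the one under which the package
reproduces the published numbers.

**Odds-ratio back-transformation (`method`).** The exact odds-scale
inversion is $p_c = o/(1+o)$ with $o = \frac{p_t/(1-p_t)}{\mathrm{OR}}$
(`apply_odds_ratio()`, `method = "odds"`). The alternative reads the
published odds ratios as risk ratios: $p_c = p_t/\mathrm{OR}$
(`method = "ratio"`). With exact odds inversion the model understates the
published QALY gains by roughly 40% (30-year increment 0.25 vs the
published 0.422); with the ratio reading it reproduces them to within a few
percent across the base case and every one-way extreme we can check. For
common outcomes such as mRS 0–1 (probabilities near 0.5) the two differ
substantially; for rare ones (sICH) they almost agree. The package
therefore defaults to `"ratio"` — as a reproduction finding, not as an
endorsement: on odds-scale estimates the `"odds"` method is the
mathematically correct inversion, and both are first-class code paths.

**Life table (`interp`).** Only two anchor rates of the age-specific
non-stroke death schedule are printed: 0.0089 at age 63 and 0.1654 at
age 93. Intermediate ages are interpolated log-linearly (constant annual
growth factor, `r round(exp(log(0.1654/0.0089)/30), 4)` per year), because
adult mortality hazards grow approximately exponentially with age
(Gompertz-like). A `"linear"` variant exists for sensitivity checks. Ages
beyond 93 keep the age-93 rate; with a 30-year horizon from age 63 this
affects nothing in the base case. The unknown shape of the source's full
life table is the dominant irreducible source of reproduction error at long
horizons, which is why reproduction checks use proportional tolerances
rather than printed precision.

**Cycle structure and year marks.** The model has one 90-day decision-tree
cycle (0.25 years: occupancy at the 90-day distribution, index
hospitalization costs, QALY accrual of 0.25 years at the 90-day state
utilities) followed by annual cycles. Because that grid never lands on
integer years, an $H$-year figure is read as cycle 0, annual cycles $1$
through $H-1$ in full, and 0.75 of annual cycle $H$ — exactly $H$ years of
coverage. Discounting starts at the first annual cycle with factor
$(1+r)^{-y}$; cycle-0 flows are undiscounted. No half-cycle correction is
applied — none is described in the source — and this is part of the
explicit discrepancy budget.

**Event ordering.** Recurrence (and its case fatality) resolves before
non-stroke mortality, and recurrent-stroke survivors are not additionally
exposed to non-stroke death in the same cycle. This avoids double-counting
mortality; the source states no ordering. Recurrence applies to all alive
states, including mRS 0–1, since the registry recurrence rate is
cohort-wide.

**sICH accounting.** sICH is priced as a first-cycle cost add-on only; its
clinical consequences are taken as already embedded in the observed 90-day
distributions. The control arm also accrues the add-on, at its
back-transformed sICH rate — a symmetry assumption the source does not
state either way (the control sICH rate is small, so the choice moves the
incremental cost by only a few CNY).

**Utility sets.** The published 1-year per-arm QALY levels (0.655 no-tPA,
0.711 tPA) sit between what the base-range utilities (0.80/0.58/0.28) and
the upper-range set (0.95/0.78/0.36) produce; incremental results barely
depend on the choice. Rather than silently picking one,
`run_base_case(utilities = "both")` tabulates both, and the reproduction
checks assert increments (which are robust), not per-arm levels.

## Probabilistic sensitivity analysis

All inputs vary jointly and independently:

- *Probabilities and utilities* — beta, by method of moments with mean at
  the base value and the printed range read as a central 95% interval
  (SD = range/3.92; the divisor is configurable). Infeasible moment
  solutions fall back to uniform(low, high) with a warning.
- *Costs, odds ratios, hazard ratios, the recurrence escalation factor* —
  lognormal, log-median at the base value, log-SD = (log high − log
  low)/3.92. Odds ratios use their 95% CI bounds, the standard scale on
  which OR intervals are constructed.
- *Window outcome distributions* — the four mRS margins are drawn as beta
  variables with effective sample size $n_w = 1128 \times \text{share}_w$
  (their binomial sampling uncertainty in the source registry) and
  renormalized to sum to 1; a Dirichlet option (`psa.window_model:
  dirichlet` in the config) is exposed because the multivariate handling is
  not specified. sICH rates are beta with the same $n_w$. Setting
  `window_model: fixed` pins them, which together with degenerate ranges
  collapses the PSA onto the deterministic base case (a tested property).
- *Discount rates* — sampled like the other probability-scale inputs, since
  the source varied all inputs simultaneously and prints ranges for both.
- Hazard-ratio draws are sorted to restore the ordering
  HR(mRS 0–1) ≤ HR(2–3) ≤ HR(4–5) implied by the state definitions.

Each of the 10,000 draws reruns both arms to 30 years; invalid draws
(back-transformed probabilities outside $[0,1]$) are resampled and counted,
with an abort above 1%. The acceptability curve reports, per
willingness-to-pay $\lambda$ on a grid from 0 to 200,000 CNY (including
35,100 and 105,000 exactly), the fraction of draws with positive net
monetary benefit $\lambda\,\Delta Q - \Delta C$. One seeded generator
stream drives the whole run; the seed is recorded in the result and the
run is bitwise reproducible.

With this parameterization the model reproduces the published fraction
cost-effective at CNY 105,000 (98.7%) and the dominant-quadrant fraction
(14.4%) to well within a percentage point, but puts about 86% (not the
published 79.2%) of draws below CNY 35,100: our ICER distribution carries
less mass between the two thresholds. The exact published mapping from
ranges to distribution parameters is unknown, and we deliberately did not
search parameterizations to hit that third figure; the corresponding check
is left failing with this explanation rather than loosened.

## The synthetic-data generator and what tests show

`simulate_patients()` draws patient tables with the registry cohort's
marginal structure — age ~ N(63.48, 11.34²) truncated to [18, 95], 39.01%
female, windows by share, 90-day state from the arm's window distribution,
sICH by window rate. Age, sex and NIHSS are descriptive columns only: the
cohort model intentionally conditions on none of them (it runs a single
start age of 63), so the generator mirrors the cohort description without
inventing covariate effects. It emulates sampling noise around the model's
own probabilities; it does *not* emulate anything the model omits —
covariate-dependent treatment effects, secular trends in care, correlated
outcomes within centers, post-stroke functional improvement — so passing
parameter-recovery tests validates the estimation machinery, not the
model's fidelity to real patients.

`microsim_oracle()` is the validation instrument for the cohort engine: it
draws every transition the engine computes in expectation as an individual
Bernoulli/categorical event, with identical probabilities and ordering, and
shares no code with the engine's expected-value recursion. Agreement of its
means with the cohort totals (tested at 100,000 patients, horizons 1, 5 and
30 years, both arms, 3 Monte-Carlo SEs) is a two-sided consistency check.

## Numerical conventions and test problem sizes

- Occupancy vectors are checked to sum to 1 within 1e-9 every cycle; the
  printed window distributions (rounded to two decimals) are renormalized
  exactly once at load, and deviations beyond 0.5 pp are errors.
- Degenerate inputs: odds back-transformation refuses $p \in \{0, 1\}$;
  ratio back-transformation refuses results ≥ 1; inconsistent odds ratios
  (back-transformed mRS 0–1 + death mass exceeding 1) name the offending
  window. One-way sweeps that produce an invalid model (e.g. the
  HR(mRS 0–1) upper bound 1.2 crossing HR(2–3) = 1.19) are flagged entries,
  never dropped silently.
- ICERs are kept unrounded in machine output; any display rounding never
  feeds computation.
- Test sizes were chosen to make Monte-Carlo error small relative to the
  asserted tolerances: 10,000 PSA draws (matching the published run),
  100,000-patient microsimulations for engine validation, 200 replicates of
  the 1,128-patient cohort for interval coverage, 100,000-patient draws for
  frequency recovery. The full suite runs in about half a minute.

## Known limitations

- The control arm is a model construct, not observed data; everything
  downstream inherits the back-transformation reading discussed above.
- The life table between ages 63 and 93 is a one-parameter reconstruction
  of a schedule the source had in full.
- No tunnel states (time-since-recurrence effects), no non-stroke
  cardiovascular events, no rehabilitation-driven improvement, no indirect
  or caregiving costs — matching the source's own scope.
- Costs are 2011 CNY throughout; `cny_to_usd()` is display-only and no
  price-index machinery is included.
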