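---
title: "A Markov cohort model for natalizumab treatment strategies in pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for natalizumab treatment strategies in pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natcea)
```

## The decision problem

Women with relapsing–remitting multiple sclerosis (MS) who become pregnant
while on natalizumab — a high-efficacy disease-modifying treatment given as
a 4-weekly intravenous infusion — face a treatment decision with both
clinical and economic consequences. Stopping the drug raises the risk of
relapse (including rebound activity in pregnancy) and of disability
progression on the Expanded Disability Status Scale (EDSS); continuing it
costs drug acquisition and administration money. `natcea` models three
strategies from a national healthcare system perspective:

* **stop at conception** — no further infusions after the first positive
  pregnancy test, resume post-pregnancy (the reference strategy);
* **stop after the first trimester**;
* **continue through pregnancy**.

## Model structure

The model is a deterministic Markov **cohort** simulation in monthly
cycles: 12 months pre-conception, 9 months of pregnancy and 12 months
post-pregnancy, a 33-month horizon. Every woman advances from one cycle to
the next with probability 1; nothing is sampled at the individual level.
The cohort is stratified into three EDSS bands (0–1, 2–3, 4+). Each cycle,
for the strategy under evaluation:

1. the pregnancy **phase** determines the annualised relapse rate (ARR);
2. expected relapses are the occupancy-weighted monthly relapse
   probability, $1 - e^{-\mathrm{ARR}/12}$;
3. **progression** moves band mass one band upward (4+ absorbs) at a
   constant monthly hazard;
4. discounted **costs** accrue: relapses × cost per relapse, EDSS band
   occupancy × annual band cost / 12, and the drug cost stream;
5. discounted **QALYs** accrue: occupancy-weighted band utility / 12 minus
   relapse disutility, floored at zero per cycle.

Totals are sums over all 33 cycles. Costs and QALYs are discounted at
3.5%/yr, the UK health-technology-appraisal convention, as
$(1+r)^{-t/12}$ with cycle 0 undiscounted.

Incremental analysis versus the reference uses the incremental
cost-effectiveness ratio $\mathrm{ICER} = \Delta C / \Delta E$ and the net
monetary benefit $\mathrm{NMB} = \lambda\,\Delta E - \Delta C$ at
willingness-to-pay $\lambda$ (£20,000/QALY by default; £30,000 as a
scenario). A strategy is cost-effective iff NMB > 0, a strict inequality.

## Parameters

All inputs ship as the packaged base case
(`system.file("extdata", "base_case.yaml", package = "natcea")`); any field
can be overridden from a YAML file via `load_parameters()`.

```{r}
p <- default_parameters()
p
```

The key inputs, with units and defaults:

* **ARRs** (events/person-year), per strategy × phase, printed as closed
  intervals (e.g. 0.5–0.6 during pregnancy after stopping at conception).
  The deterministic base case reduces each interval to its **midpoint** —
  the symmetric choice absent a stated reduction rule — and the PSA
  explores the surrounding range.
* **EDSS progression over the horizon**: 21% / 16% / 12% of the cohort.
  The continuation value is not observed directly; it is derived from the
  linear relationship $y = -4.58x + 25.63$ (percent) in the strategy index
  $x \in \{1,2,3\}$, which reproduces 21.05 / 16.47 / 11.89 — the tabulated
  values to rounding (`progression_linear()`). A logarithmic alternative
  through the two observed anchors (`progression_log()`, 13.08% at
  $x = 3$) drives the scenario analysis.
* **Baseline EDSS occupancy** 53.9% / 35.6% / 5.9% and band utilities
  0.88 / 0.75 / 0.43 (per year of full health); relapse disutility 0.07
  QALY per event, taken as an absolute decrement per event.
* **Costs (GBP, 2024 prices)**: drug acquisition £1130 (originator) /
  £870 (generic) / £666 (biosimilar) and administration £223, both per
  4-weekly cycle; £1623 per relapse; annual direct cost per EDSS level 0–9
  from £488 to £35,545. No currency or price-year machinery is included.
* **Drug cycles** over the horizon: 6 / 6.75 / 8.25 per strategy. These
  printed totals are taken as authoritative inputs; they are not derivable
  from the 4-weekly frequency alone.

## Numerical conventions and open choices

Several conventions the results depend on are not dictated by the inputs;
each is a documented, configurable decision:

* **Residual occupancy.** The baseline band occupancies sum to 0.954. The
  default carries the residual 0.046 as an inert, zero-cost, zero-utility
  *unclassified* stratum (`edss$residual = "unclassified"`); the
  alternative renormalises the three bands onto the simplex
  (`"renormalise"`). We made the unclassified stratum the default because
  renormalisation inflates the cohort's QALY mass by ~4.8%, pushing every
  strategy's total QALYs (≈1.96–2.03) above the published 1.90–1.94 range,
  whereas the unclassified reading reproduces all three published QALY
  totals to within 0.03. The unclassified stratum neither relapses nor
  progresses, so expected relapses scale with the classified mass 0.954.
* **EDSS band costs.** The cost ladder prices individual levels 0–9 but
  the cohort is banded. The default band cost is the unweighted mean of
  the member levels (0–1: £687.50; 2–3: £4,133.50; 4+: £16,111.50/yr);
  the 4+ aggregation range is exposed as `edss$band_levels[[3]]` because
  the within-band case mix is unknown and the choice moves absolute costs
  by thousands of pounds. We examined narrower, costlier aggregations
  (levels 6–9, upper levels only) and kept the full-range mean: it is the
  only setting that keeps all strategies' total costs within 5% of the
  published totals.
* **Rate → probability**: the exponential constant-hazard transform, not
  ARR/12; the difference is <0.2% at these rates.
* **Progression spreading**: the horizon-level proportion becomes a
  constant monthly hazard, $1-(1-P)^{1/33}$, moving exactly one band per
  event; progression is applied before accrual within a cycle.
* **Drug cost timing**: each strategy's total drug cost (cycles × unit
  cost) is spread uniformly over its on-treatment months (pre-conception
  only; plus the first trimester; plus the whole pregnancy). Undiscounted
  streams sum exactly to the totals; discounting perturbs them by <1%.
* **QALY floor**: per-cycle QALY increments are floored at zero so extreme
  PSA draws cannot accrue negative life quality.
* **ICER conventions**: the ICER is reported as undefined (`NA`), not
  infinite, when ΔE = 0; dominance ("dominant"/"dominated") is classified
  from the signs of ΔC and ΔE, and dominated/dominant rows still carry
  their NMB so result tables can be fully populated.

## Probabilistic sensitivity analysis

The PSA perturbs ARR point values, progression proportions, baseline
occupancy, and all costs by "±20%", read as the **95% interval** of the
perturbation distribution: sd = 0.2 × mean / 1.96. Proportions and rates
use a moment-matched beta distribution (rescaled onto $[0, 2m]$ for rates
above 0.95, with a gamma fallback if infeasible — not needed at the base
values); costs use a moment-matched gamma. Utilities, cycle counts, the
schedule and the discount rate are held fixed. Within a draw all three
strategies share the same perturbed parameter set (correlated PSA), while
strategy-specific inputs are drawn independently of each other — no
correlation structure is imposed beyond sharing.

The default run is 1000 draws (`run_psa()`, seeded and bit-reproducible).
The cost-effectiveness acceptability curve (`ceac()`) reports, per
willingness-to-pay value on a £0–£50,000 grid in £1,000 steps, the
fraction of draws in which each strategy has the strictly highest NMB,
with exact ties sharing a draw equally, so probabilities sum to one at
every grid point.

```{r, fig.width = 6, fig.height = 4}
psa <- run_psa(default_parameters(), n_draws = 200, seed = 1)
plot(ceac(psa))
```

## Scenario analyses

`standard_scenarios()` names the five analyses: the base case, the generic
and biosimilar price variants (prices touch only costs, so per-strategy
QALYs are bitwise identical across variants), the logarithmic-progression
variant (which re-derives only the continuation proportion from the two
observed anchors), and the £30,000/QALY threshold. `run_all_scenarios()`
runs them end to end from one call and a single summary table.

## Synthetic parameter sets and validation

`generate_parameter_sets()` emits dispersed but structurally valid
parameter sets: ARR midpoints within plausible relapsing-MS magnitudes,
band-aggregated cost ladders kept nondecreasing, utilities decreasing
across bands, occupancies sub-simplex, everything reproducible from a
seed. These sets exist to exercise the machinery — they emulate the
*shape* of the inputs, not any real population, and carry no patient-level
heterogeneity, covariates or longitudinal noise; tests passing on them
demonstrate internal correctness of the accounting, not external validity
of the model. `known_answer_fixture()` supplies degenerate sets with
closed-form totals (e.g. a single band at utility 0.75 with everything
else switched off accrues exactly 33 × 0.75/12 = 2.0625 QALYs), and the
test suite checks the engine against an independent closed-form occupancy
accumulation on 50 generated sets.

Problem sizes used throughout the tests and the acceptance script — 33
cycles × 3 strategies deterministically, 1000 PSA draws, 50–100 generated
sets for property checks, 10,000 draws for moment-recovery checks — keep a
full run in the low seconds while leaving Monte Carlo error on CEAC
probabilities near 0.01.

## Known limitations

* Cohort expectations only: no individual-level microsimulation, no
  sampled trajectories, no mortality, no EDSS improvement, no washout
  period.
* Neonatal outcomes, breastfeeding effects on relapse, and dosing-interval
  variation are out of scope.
* The drug-cycle totals and the within-band EDSS case mix are taken as
  given; both are structural inputs the data cannot identify.
* Published incremental results for this decision problem are not fully
  reconcilable with the published inputs (the middle strategy's printed
  total cost exceeds any value reachable from its uniformly more
  favourable inputs plus 0.75 extra drug cycles); where that happens the
  package reports what the inputs imply rather than the printed numbers.
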