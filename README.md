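# natcea

Cost-effectiveness analysis of natalizumab treatment strategies for
pregnant women with relapsing multiple sclerosis, from the UK healthcare
system perspective.

Natalizumab is a high-efficacy disease-modifying treatment given by
4-weekly infusion. Around pregnancy, women and clinicians must decide
whether to stop it at conception (risking relapse rebound and disability
progression), stop after the first trimester, or continue throughout
pregnancy (incurring ongoing drug costs). `natcea` implements a
deterministic Markov cohort model of the three strategies over a 33-month
horizon (12 months pre-conception, 9 of pregnancy, 12 post-pregnancy) in
monthly cycles, tracking EDSS disability-band occupancy, relapse events,
costs and quality-adjusted life years (QALYs), discounted at 3.5%/yr.

The economics on top of the engine follow standard health-technology
appraisal: for each strategy versus discontinuation at conception,

* ICER = ΔC / ΔE, the incremental cost per QALY gained, judged against a
  willingness-to-pay threshold λ (£20,000/QALY);
* NMB = λ·ΔE − ΔC, the net monetary benefit, with NMB > 0 meaning
  cost-effective and dominance classified from the signs of ΔC and ΔE.

Uncertainty is quantified by a probabilistic sensitivity analysis (PSA):
1000 parameter draws with ±20% perturbations (moment-matched beta for
rates/proportions, gamma for costs), summarised as cost-effectiveness
planes and acceptability curves (CEAC). Scenario analyses swap in generic
or biosimilar drug prices, a logarithmic disability-progression
interpolation, and a £30,000/QALY threshold.

## Worked example

```r
library(natcea)

params <- default_parameters()        # packaged base-case inputs
res    <- run_strategies(params)      # one cohort run per strategy
render_results(results_table(res), incremental_table(res))
```

```
                    strategy total cost (£) total QALYs ΔC (£) ΔE (QALY)   ICER NMB (£)
1         stop_at_conception         19,187        1.87      -         -      -       -
2 stop_after_first_trimester         19,438        1.90    250      0.02 10,461     228
3 continue_through_pregnancy         20,331        1.94  1,144      0.06 18,398     100
```

Per person over the 33 months, stopping at conception costs £19,187 and
yields 1.87 QALYs; continuing through pregnancy buys 0.06 extra QALYs for
an extra £1,144 — an ICER of £18,398/QALY, under the £20,000 threshold
(NMB +£100), so continuation is cost-effective but by a narrow margin.
Stopping after the first trimester is also cost-effective versus stopping
at conception (ICER £10,461/QALY).

```r
psa <- run_psa(params, n_draws = 1000, seed = 1)
probability_cost_effective(psa, "continue_through_pregnancy", 20000)
#> [1] 0.262
probability_cost_effective(psa, "continue_through_pregnancy", 30000)
#> [1] 0.613
plot(ceac(psa))     # acceptability curves, £0-£50,000
```

With base-case NMBs this close to zero, the PSA spreads the decision: the
probability that continuation has the highest NMB is 0.262 at
£20,000/QALY, rising with the threshold to 0.613 at £30,000/QALY.

Scenarios (`run_all_scenarios()`) show the expected price effects:
per-strategy QALYs are identical across price variants, and the
continuation strategy's NMB rises as the acquisition price falls from
originator (£1130) to generic (£870) to biosimilar (£666).

A thin command-line front end ships at `inst/cli/natcea.R`
(`Rscript natcea.R base-case|psa|scenarios|generate-fixtures ...`).

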