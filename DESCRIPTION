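Package: natcea
Title: Cost-Effectiveness of Natalizumab Treatment Strategies in Pregnancy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A Markov cohort cost-effectiveness model comparing three
    natalizumab treatment strategies for pregnant women with relapsing
    multiple sclerosis (continue through pregnancy, stop after the first
    trimester, stop at conception), over a 33-month monthly-cycle horizon
    spanning 12 months pre-conception, 9 months of pregnancy and 12 months
    post-pregnancy. Accrues discounted costs (drug acquisition and
    administration, relapse events, EDSS-band disability costs) and
    quality-adjusted life years, computes incremental cost-effectiveness
    ratios and net monetary benefit against a willingness-to-pay threshold,
    runs probabilistic sensitivity analysis with moment-matched beta and
    gamma parameter perturbations, derives cost-effectiveness acceptability
    curves, and orchestrates drug-price and progression-function scenario
    analyses. Includes a synthetic parameter-set generator and closed-form
    known-answer fixtures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
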