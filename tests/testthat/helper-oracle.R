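# Independent brute-force accumulation of cohort totals under zero (or any)
# discounting, using closed-form band occupancies instead of the engine's
# iterative update:
#   b1(k) = b1_0 * q^k
#   b2(k) = q^k * (b2_0 + b1_0 * k * p / q),  q = 1 - p
#   b3(k) = S - b1(k) - b2(k)
# Accrual at cycle t uses occupancy after k = t + 1 progression steps
# (progression precedes accrual), relapse expectation uses the conserved
# total band mass S.
oracle_cohort <- function(strategy, params) {
  H <- horizon_months(params)
  occ0 <- effective_occupancy(params)$bands
  S <- sum(occ0)
  band_cost <- edss_band_costs(params)
  util <- params$edss$band_utility
  mids <- vapply(params$relapse_rates[[strategy]], mean, numeric(1))
  P <- params$progression$proportions[[strategy]]
  p <- 1 - (1 - P)^(1 / H)
  q <- 1 - p
  drug <- drug_cost_schedule(strategy, params$drug, params$schedule)
  rate <- params$settings$annual_discount_rate

  cost <- qaly <- 0
  for (t in 0:(H - 1)) {
    k <- t + 1
    b1 <- occ0[1] * q^k
    b2 <- q^k * (occ0[2] + occ0[1] * k * p / q)
    b3 <- S - b1 - b2
    occ <- c(b1, b2, b3)
    ph <- phase_of_cycle(t, params$schedule)
    exp_rel <- S * (1 - exp(-mids[[ph]] / 12))
    df <- (1 + rate)^(-t / 12)
    cost <- cost + df * (exp_rel * params$relapse_econ$cost_per_relapse +
                           sum(occ * band_cost) / 12 +
                           drug$acquisition[k] + drug$administration[k])
    qaly <- qaly + df * max(0, sum(occ * util) / 12 -
                              exp_rel * params$relapse_econ$disutility_per_relapse)
  }
  list(total_cost = cost, total_qaly = qaly)
}

# minimal strategy result for economics-only tests
make_result <- function(cost, qaly, strategy = "continue_through_pregnancy",
                        wtp = 20000, rate = 0.035) {
  structure(list(strategy = strategy, total_cost = cost, total_qaly = qaly,
                 breakdown = NULL,
                 settings = list(annual_discount_rate = rate,
                                 wtp_threshold = wtp,
                                 price_variant = "originator")),
            class = "natcea_result")
}

zero_discount <- function(params) {
  params$settings$annual_discount_rate <- 0
  params
}
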