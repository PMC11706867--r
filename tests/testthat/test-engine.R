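test_that("rate and discount conversions match their closed forms", {
  expect_equal(monthly_relapse_probability(0), 0)
  expect_equal(monthly_relapse_probability(0.29), 1 - exp(-0.29 / 12))
  expect_equal(monthly_relapse_probability(0.29), 0.0238766, tolerance = 1e-4)
  expect_equal(monthly_relapse_probability(0.55), 0.0447966, tolerance = 1e-4)
  expect_error(monthly_relapse_probability(-0.1), ">= 0")

  expect_equal(monthly_discount_factor(0.035, 0), 1)
  expect_equal(monthly_discount_factor(0.035, 12), 1 / 1.035)
  expect_equal(monthly_discount_factor(0.035, 32), 1.035^(-32 / 12))
  expect_error(monthly_discount_factor(1, 0), "\\[0, 1\\)")

  expect_equal(monthly_progression_probability(0, 33), 0)
  expect_equal(monthly_progression_probability(0.21, 33), 1 - 0.79^(1 / 33))
  expect_equal(monthly_progression_probability(0.21, 33), 0.0071176, tolerance = 1e-4)
  expect_equal(monthly_progression_probability(0.12, 33), 0.0038662, tolerance = 1e-4)
  expect_error(monthly_progression_probability(1, 33), "\\[0, 1\\)")
})

test_that("cycles map onto pregnancy phases at the schedule boundaries", {
  s <- default_parameters()$schedule
  expect_identical(phase_of_cycle(0, s), "pre_conception")
  expect_identical(phase_of_cycle(11, s), "pre_conception")
  expect_identical(phase_of_cycle(12, s), "pregnancy")
  expect_identical(phase_of_cycle(20, s), "pregnancy")
  expect_identical(phase_of_cycle(21, s), "post_pregnancy")
  expect_identical(phase_of_cycle(32, s), "post_pregnancy")
  expect_error(phase_of_cycle(33, s), "horizon")
  expect_error(phase_of_cycle(-1, s), "horizon")
  # general schedules are honoured
  s2 <- list(pre_conception_months = 2L, pregnancy_months = 3L,
             post_pregnancy_months = 1L)
  expect_identical(phase_of_cycle(2, s2), "pregnancy")
  expect_identical(phase_of_cycle(5, s2), "post_pregnancy")
})

test_that("drug cost streams sum to cycles times unit cost, over on-treatment months", {
  p <- default_parameters()
  sch <- drug_cost_schedule("stop_at_conception", p$drug, p$schedule)
  expect_equal(sum(sch), 6 * (1130 + 223)) # 8118
  expect_equal(sum(rowSums(sch)[1:12] > 0), 12)
  expect_equal(unname(rowSums(sch)[13:33]), rep(0, 21))

  p$drug$price_variant <- "biosimilar"
  sch2 <- drug_cost_schedule("continue_through_pregnancy", p$drug, p$schedule)
  expect_equal(sum(sch2), 8.25 * (666 + 223)) # 7334.25
  expect_equal(sum(rowSums(sch2) > 0), 21) # pre-conception + pregnancy

  sch3 <- drug_cost_schedule("stop_after_first_trimester", p$drug, p$schedule)
  expect_equal(sum(rowSums(sch3) > 0), 15) # pre-conception + first trimester

  p$drug$total_cycles[] <- 0
  expect_equal(sum(drug_cost_schedule("stop_at_conception", p$drug, p$schedule)), 0)
})

test_that("known-answer fixtures match the engine to closed form", {
  for (nm in c("null_model", "flat_utility", "pure_drug")) {
    fx <- known_answer_fixture(nm)
    r <- run_cohort(fx$strategy, fx$params)
    expect_equal(r$total_cost, fx$expected$total_cost, tolerance = 1e-9)
    expect_equal(r$total_qaly, fx$expected$total_qaly, tolerance = 1e-9)
  }
  expect_equal(known_answer_fixture("flat_utility")$expected$total_qaly, 2.0625)
  expect_equal(known_answer_fixture("pure_drug")$expected$total_cost, 8118)
  expect_error(known_answer_fixture("nope"), "unknown fixture")
})

test_that("engine totals equal the independent closed-form accumulation", {
  sets <- generate_parameter_sets(n_sets = 50, seed = 7, jitter = 0.2)
  for (p in sets) {
    p0 <- zero_discount(p)
    for (s in natcea_strategies) {
      r <- run_cohort(s, p0, validate = FALSE)
      o <- oracle_cohort(s, p0)
      expect_equal(r$total_cost, o$total_cost, tolerance = 1e-9)
      expect_equal(r$total_qaly, o$total_qaly, tolerance = 1e-9)
    }
  }
  # the oracle also reproduces the discounted base case
  p <- default_parameters()
  r <- run_cohort("continue_through_pregnancy", p)
  o <- oracle_cohort("continue_through_pregnancy", p)
  expect_equal(r$total_cost, o$total_cost, tolerance = 1e-9)
})

test_that("band occupancy mass is conserved at every cycle", {
  sets <- generate_parameter_sets(n_sets = 100, seed = 11, jitter = 0.25)
  for (p in sets) {
    occ <- effective_occupancy(p)
    total0 <- sum(occ$bands)
    r <- run_cohort(sample(natcea_strategies, 1), p, trace = TRUE,
                    validate = FALSE)
    sums <- rowSums(r$trace[, paste0("occ_", p$edss$bands)])
    expect_true(all(abs(sums - total0) < 1e-12))
    expect_true(all(abs(r$trace$unclassified - occ$unclassified) < 1e-12))
  }
})

test_that("costs rise with relapse rates and QALYs rise with utilities", {
  set.seed(19)
  p <- default_parameters()
  for (i in 1:100) {
    s <- sample(natcea_strategies, 1)
    ph <- sample(c("pre_conception", "pregnancy", "post_pregnancy"), 1)
    bump <- runif(1, 0.05, 0.5)
    p2 <- p
    p2$relapse_rates[[s]][[ph]] <- p$relapse_rates[[s]][[ph]] + bump
    r1 <- run_cohort(s, p, validate = FALSE)
    r2 <- run_cohort(s, p2, validate = FALSE)
    expect_gte(r2$total_cost, r1$total_cost)
    expect_lte(r2$total_qaly, r1$total_qaly)

    b <- sample(3, 1)
    p3 <- p
    p3$edss$band_utility[b] <- min(1, p$edss$band_utility[b] + runif(1, 0, 0.1))
    r3 <- run_cohort(s, p3, validate = FALSE)
    expect_gte(r3$total_qaly, r1$total_qaly)
  }
})

test_that("discounting can only shrink totals, with equality at rate zero", {
  p <- default_parameters()
  for (s in natcea_strategies) {
    rd <- run_cohort(s, p)
    ru <- run_cohort(s, zero_discount(p))
    expect_lt(rd$total_cost, ru$total_cost)
    expect_lt(rd$total_qaly, ru$total_qaly)
    expect_equal(run_cohort(s, zero_discount(p))$total_cost, ru$total_cost)
  }
})

test_that("base-case strategy ordering is continue > stop-after-T1 > stop", {
  res <- run_strategies(default_parameters())
  q <- vapply(res, `[[`, numeric(1), "total_qaly")
  expect_true(q[["continue_through_pregnancy"]] >
                q[["stop_after_first_trimester"]])
  expect_true(q[["stop_after_first_trimester"]] > q[["stop_at_conception"]])
})

test_that("cost breakdown components sum to the total", {
  res <- run_strategies(default_parameters())
  for (r in res) {
    expect_equal(r$total_cost,
                 sum(r$breakdown[c("drug_acquisition", "drug_administration",
                                   "relapse_cost", "edss_cost")]),
                 tolerance = 1e-9)
    expect_equal(r$total_qaly,
                 r$breakdown[["qaly_edss"]] - r$breakdown[["qaly_relapse_loss"]],
                 tolerance = 1e-9)
  }
})

test_that("per-cycle traces export to CSV with audit columns", {
  r <- run_cohort("stop_at_conception", default_parameters(), trace = TRUE)
  expect_equal(nrow(r$trace), 33)
  expect_true(all(c("cycle", "phase", "expected_relapses", "discount_factor",
                    "edss_cost", "qaly_edss") %in% names(r$trace)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(r, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 33)
  expect_error(write_trace_csv(run_cohort("stop_at_conception",
                                          default_parameters()), f),
               "no trace")
})
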