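test_that("PSA output is bit-identical under a fixed seed", {
  p <- default_parameters()
  a <- run_psa(p, n_draws = 25, seed = 99)
  b <- run_psa(p, n_draws = 25, seed = 99)
  expect_identical(a$samples, b$samples)
  expect_identical(as.data.frame(ceac(a)), as.data.frame(ceac(b)))
  c2 <- run_psa(p, n_draws = 25, seed = 100)
  expect_false(identical(a$samples, c2$samples))
})

test_that("a zero perturbation range degenerates to the deterministic base case", {
  p <- default_parameters()
  expect_identical(draw_parameters(p, range = 0, seed = 5), p)
  psa <- run_psa(p, n_draws = 1, seed = 5, range = 0)
  det <- run_strategies(p)
  for (s in natcea_strategies) {
    expect_equal(psa$samples$total_cost[psa$samples$strategy == s],
                 det[[s]]$total_cost)
    expect_equal(psa$samples$total_qaly[psa$samples$strategy == s],
                 det[[s]]$total_qaly)
  }
})

test_that("perturbation distributions recover the stated moments", {
  p <- default_parameters()
  set.seed(1234)
  n <- 10000
  cost <- prog <- arrp <- numeric(n)
  for (i in seq_len(n)) {
    d <- draw_parameters(p)
    cost[i] <- d$relapse_econ$cost_per_relapse
    prog[i] <- d$progression$proportions[["stop_at_conception"]]
    arrp[i] <- d$relapse_rates$stop_at_conception$pregnancy[1]
  }
  # gamma: mean 1623, sd 0.2 * 1623 / 1.96
  expect_equal(mean(cost), 1623, tolerance = 0.01)
  expect_equal(sd(cost), 0.2 * 1623 / 1.96, tolerance = 0.1)
  # beta: mean 0.21 (progression) and 0.55 (pregnancy ARR midpoint)
  expect_equal(mean(prog), 0.21, tolerance = 0.01)
  expect_equal(mean(arrp), 0.55, tolerance = 0.01)
  expect_equal(sd(arrp), 0.2 * 0.55 / 1.96, tolerance = 0.1)
  expect_true(all(prog >= 0 & prog <= 1))
  expect_true(all(cost >= 0))
})

test_that("perturbed parameter sets keep proportions and costs in range", {
  p <- default_parameters()
  set.seed(77)
  for (i in 1:100) {
    d <- draw_parameters(p)
    expect_true(all(d$edss$baseline_occupancy >= 0 &
                      d$edss$baseline_occupancy <= 1))
    expect_lte(sum(d$edss$baseline_occupancy), 1 + 1e-12)
    expect_true(all(unlist(d$relapse_rates) >= 0))
    expect_true(all(d$edss$level_costs >= 0))
    # held-fixed blocks stay fixed
    expect_identical(d$edss$band_utility, p$edss$band_utility)
    expect_identical(d$drug$total_cycles, p$drug$total_cycles)
    expect_identical(d$settings, p$settings)
  }
})

test_that("PSA bookkeeping: one outcome pair per draw and strategy", {
  psa <- run_psa(default_parameters(), n_draws = 40, seed = 3)
  expect_equal(nrow(psa$samples), 40 * 3)
  plane <- ce_plane(psa)
  expect_equal(nrow(plane), 40 * 2) # both non-reference strategies
  expect_true(all(abs(plane$incremental_cost) < 5e4))
})

test_that("CEAC probabilities sum to one at every threshold", {
  psa <- run_psa(default_parameters(), n_draws = 60, seed = 8)
  cc <- ceac(psa, wtp_grid = seq(0, 50000, by = 500))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
})

test_that("CEAC limit and dominance cases behave as expected", {
  # lambda = 0: the cheapest strategy per draw wins
  s <- data.frame(
    draw = rep(1:4, each = 3),
    strategy = rep(natcea_strategies, 4),
    total_cost = c(10, 20, 30,  5, 50, 6,  9, 8, 7,  1, 2, 3),
    total_qaly = rep(c(1, 2, 3), 4)
  )
  cc0 <- ceac(s, wtp_grid = 0)
  expect_equal(cc0$probability[cc0$strategy == "stop_at_conception"], 0.75)
  expect_equal(cc0$probability[cc0$strategy == "continue_through_pregnancy"], 0.25)
  expect_equal(cc0$probability[cc0$strategy == "stop_after_first_trimester"], 0)

  # a strategy cheaper and more effective in every draw wins at every lambda
  dom <- data.frame(
    draw = rep(1:5, each = 3),
    strategy = rep(natcea_strategies, 5),
    total_cost = rep(c(30, 20, 10), 5),
    total_qaly = rep(c(1, 1.1, 2), 5)
  )
  ccd <- ceac(dom, wtp_grid = c(0, 10000, 50000))
  expect_true(all(ccd$probability[ccd$strategy == "continue_through_pregnancy"] == 1))

  # exact ties split their draw equally
  tie <- data.frame(draw = rep(1, 3), strategy = natcea_strategies,
                    total_cost = c(10, 10, 99), total_qaly = c(1, 1, 0))
  cct <- ceac(tie, wtp_grid = 1000)
  expect_equal(cct$probability, c(0.5, 0.5, 0))

  expect_error(ceac(s[0, ], wtp_grid = 0), "empty")
  expect_error(ceac(s, wtp_grid = c(10, 5)), "ascending")
})

test_that("with a positive QALY gain in every draw, acceptability rises with lambda", {
  psa <- run_psa(default_parameters(), n_draws = 150, seed = 21)
  sam <- psa$samples
  ref <- sam[sam$strategy == "stop_at_conception", ]
  alt <- sam[sam$strategy == "continue_through_pregnancy", ]
  keep <- alt$total_qaly > ref$total_qaly # configured pairwise filter
  expect_gt(sum(keep), 0)
  two <- rbind(ref[keep, ], alt[keep, ])
  two <- two[order(two$draw, match(two$strategy, natcea_strategies)), ]
  cc <- ceac(two, wtp_grid = seq(0, 50000, by = 1000))
  pr <- cc$probability[cc$strategy == "continue_through_pregnancy"]
  expect_true(all(diff(pr) >= -1e-12))
})

test_that("draws with zero-valued base parameters stay at zero", {
  p <- default_parameters()
  p$relapse_rates$continue_through_pregnancy$pregnancy <- c(0, 0)
  d <- draw_parameters(p, seed = 42)
  expect_identical(d$relapse_rates$continue_through_pregnancy$pregnancy, c(0, 0))
})
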