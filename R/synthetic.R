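# jitter a positive value multiplicatively (lognormal-ish, clamped to an
# envelope around the base so generated sets stay in a plausible range)
jitter_pos <- function(x, jitter, lo = 0.5 * x, hi = 2 * x) {
  if (jitter == 0) return(x)
  out <- pmin(hi, pmax(lo, x * exp(jitter * stats::rnorm(length(x)))))
  out[x == 0] <- 0 # zero stays zero
  out
}

#' Generate synthetic parameter sets
#'
#' Emits parameter sets with the statistical structure the analysis
#' assumes, dispersed around the packaged base case: ARR intervals with
#' `low <= high` and midpoints within plausible relapsing-MS magnitudes
#' (roughly 0.1-1 events/person-year), EDSS cost ladders whose band-level
#' aggregates stay nondecreasing, utilities decreasing across bands, and
#' occupancy vectors that remain sub-simplex. Every emitted set passes
#' [validate_parameters()]; generation is reproducible from the seed.
#'
#' @param n_sets Number of parameter sets.
#' @param seed Integer RNG seed.
#' @param jitter Relative dispersion scale; `0` reproduces the base case
#'   exactly.
#' @param randomise Which blocks to randomise: any of `"rates"` (ARRs and
#'   progression), `"costs"`, `"utilities"`, `"occupancy"`.
#' @param base Base parameter set to disperse around.
#' @return List of `natcea_params` of length `n_sets`.
#' @export
generate_parameter_sets <- function(n_sets = 1, seed = 1, jitter = 0.1,
                                    randomise = c("rates", "costs",
                                                  "utilities", "occupancy"),
                                    base = default_parameters()) {
  stopifnot(n_sets >= 1, jitter >= 0)
  randomise <- match.arg(randomise, several.ok = TRUE)
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    p <- base
    if ("rates" %in% randomise && jitter > 0) {
      for (st in natcea_strategies) {
        for (ph in names(p$relapse_rates[[st]])) {
          iv <- p$relapse_rates[[st]][[ph]]
          mid <- jitter_pos(mean(iv), jitter, lo = 0.05, hi = 1.5)
          half <- jitter_pos(max(diff(iv) / 2, 1e-12), jitter)
          if (diff(iv) == 0) half <- 0
          p$relapse_rates[[st]][[ph]] <- c(max(0, mid - half), mid + half)
        }
        pr <- jitter_pos(p$progression$proportions[[st]], jitter,
                         lo = 0.01, hi = 0.9)
        p$progression$proportions[[st]] <- pr
      }
    }
    if ("costs" %in% randomise && jitter > 0) {
      # one factor per band keeps the band-aggregate ladder nondecreasing,
      # rejection-checked after an extra per-level wobble
      repeat {
        lc <- p$edss$level_costs
        for (b in seq_along(p$edss$band_levels)) {
          lv <- p$edss$band_levels[[b]] + 1L
          f <- exp(jitter * stats::rnorm(1))
          lc[lv] <- jitter_pos(p$edss$level_costs[lv] * min(2, max(0.5, f)),
                               jitter / 2)
        }
        bc <- vapply(p$edss$band_levels, function(lv) mean(lc[lv + 1L]),
                     numeric(1))
        if (!is.unsorted(bc)) break
      }
      p$edss$level_costs <- lc
      p$relapse_econ$cost_per_relapse <-
        jitter_pos(p$relapse_econ$cost_per_relapse, jitter)
      p$drug$acquisition_cost <- jitter_pos(p$drug$acquisition_cost, jitter)
      p$drug$administration_cost <- jitter_pos(p$drug$administration_cost, jitter)
    }
    if ("utilities" %in% randomise && jitter > 0) {
      u <- pmin(1, pmax(0, jitter_pos(p$edss$band_utility, jitter)))
      p$edss$band_utility <- sort(u, decreasing = TRUE)
    }
    if ("occupancy" %in% randomise && jitter > 0) {
      occ <- jitter_pos(p$edss$baseline_occupancy, jitter)
      if (sum(occ) > 1) occ <- occ / sum(occ)
      p$edss$baseline_occupancy <- occ
    }
    p <- structure(p, class = "natcea_params")
    validate_parameters(p)
    p
  })
}

#' Known-answer fixtures with closed-form cohort results
#'
#' Hand-constructed degenerate parameter sets whose cohort totals have
#' closed forms, for oracle-testing the engine:
#' \describe{
#'   \item{`null_model`}{all costs, utilities and disutilities zero:
#'     totals (0, 0).}
#'   \item{`flat_utility`}{whole cohort in the 0-1 band at utility 0.75,
#'     no relapses, progression, drug costs or discounting: QALYs =
#'     33 x 0.75 / 12 = 2.0625, cost 0.}
#'   \item{`pure_drug`}{only originator drug costs, stop-at-conception,
#'     no discounting: cost = 6 x (1130 + 223) = 8118, QALYs 0.}
#' }
#'
#' @param name Fixture name.
#' @return List with `params`, `strategy`, and `expected` (list with
#'   `total_cost`, `total_qaly`).
#' @export
known_answer_fixture <- function(name) {
  p <- default_parameters()
  zero_rates <- function(p) {
    for (st in natcea_strategies) {
      p$relapse_rates[[st]] <- lapply(p$relapse_rates[[st]], function(x) c(0, 0))
      p$progression$proportions[[st]] <- 0
    }
    p
  }
  zero_costs <- function(p) {
    p$edss$level_costs <- rep(0, length(p$edss$level_costs))
    p$relapse_econ$cost_per_relapse <- 0
    p$drug$acquisition_cost[] <- 0
    p$drug$administration_cost <- 0
    p
  }
  switch(name,
    null_model = {
      p <- zero_costs(p)
      p$edss$band_utility <- c(0, 0, 0)
      p$relapse_econ$disutility_per_relapse <- 0
      list(params = p, strategy = "stop_at_conception",
           expected = list(total_cost = 0, total_qaly = 0))
    },
    flat_utility = {
      p <- zero_costs(zero_rates(p))
      p$edss$baseline_occupancy <- c(1, 0, 0)
      p$edss$band_utility <- c(0.75, 0, 0)
      p$relapse_econ$disutility_per_relapse <- 0
      p$settings$annual_discount_rate <- 0
      list(params = p, strategy = "stop_at_conception",
           expected = list(total_cost = 0, total_qaly = 33 * 0.75 / 12))
    },
    pure_drug = {
      p <- zero_rates(p)
      p$edss$level_costs <- rep(0, length(p$edss$level_costs))
      p$relapse_econ$cost_per_relapse <- 0
      p$edss$band_utility <- c(0, 0, 0)
      p$relapse_econ$disutility_per_relapse <- 0
      p$settings$annual_discount_rate <- 0
      list(params = p, strategy = "stop_at_conception",
           expected = list(total_cost = 6 * (1130 + 223), total_qaly = 0))
    },
    stop("unknown fixture: ", name)
  )
}
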