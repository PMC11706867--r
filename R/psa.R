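# ---- perturbation primitives ---------------------------------------------
# The ±20% variation band is read as the 95% interval of the perturbation
# distribution, so sd = range * mean / 1.96, and the named families are
# moment-matched: beta for proportions/rates, gamma for costs.

psa_sd <- function(mean, range) range * mean / 1.96

# beta draw with given mean/sd on [0, 1]; for rates whose base exceeds 0.95
# the draw is rescaled onto [0, 2 * mean] (always moment-feasible there);
# gamma is the fallback should a scaled beta still be infeasible.
perturb_proportion <- function(m, range) {
  if (m <= 0) return(m)
  s <- psa_sd(m, range)
  scale <- if (m > 0.95) 2 * m else 1
  mm <- m / scale
  ss <- s / scale
  if (ss^2 < mm * (1 - mm)) {
    k <- mm * (1 - mm) / ss^2 - 1
    scale * stats::rbeta(1, mm * k, (1 - mm) * k)
  } else {
    perturb_cost(m, range)
  }
}

# gamma draw with given mean/sd
perturb_cost <- function(m, range) {
  if (m <= 0) return(m)
  s <- psa_sd(m, range)
  stats::rgamma(1, shape = (m / s)^2, rate = m / s^2)
}

#' Draw one perturbed parameter set
#'
#' Perturbs a base parameter set as the probabilistic sensitivity analysis
#' assumes: every ARR point value (interval midpoint) and every proportion
#' (progression, baseline occupancy) is drawn from a moment-matched beta
#' distribution centred on its base value; every cost (relapse, EDSS levels,
#' drug acquisition for the active price variant, administration) from a
#' moment-matched gamma distribution; in both cases the standard deviation
#' is `range * base / 1.96` so that ±`range` spans approximately the 95%
#' interval. Utilities, drug cycle counts, the schedule and the discount
#' rate are held fixed. Base values of zero are held at zero. ARR intervals
#' collapse to perturbed point values (degenerate intervals).
#'
#' Draws consume the current RNG stream; pass `seed` to make a single call
#' reproducible ([run_psa()] seeds the stream once per run).
#'
#' @param base A validated `natcea_params` object.
#' @param range Relative perturbation half-width (default
#'   `base$settings$psa_range`); `0` returns the base set unchanged.
#' @param seed Optional integer seed set before drawing.
#' @return A `natcea_params` object with perturbed values.
#' @export
draw_parameters <- function(base, range = base$settings$psa_range, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (range == 0) return(base)
  p <- base
  for (st in natcea_strategies) {
    for (ph in names(p$relapse_rates[[st]])) {
      mid <- arr_point_value(base$relapse_rates[[st]][[ph]])
      p$relapse_rates[[st]][[ph]] <- rep(perturb_proportion(mid, range), 2)
    }
    p$progression$proportions[[st]] <-
      perturb_proportion(base$progression$proportions[[st]], range)
  }
  occ <- vapply(base$edss$baseline_occupancy, perturb_proportion,
                numeric(1), range = range)
  if (sum(occ) > 1) occ <- occ / sum(occ)
  p$edss$baseline_occupancy <- occ
  p$edss$level_costs <- vapply(base$edss$level_costs, perturb_cost,
                               numeric(1), range = range)
  p$relapse_econ$cost_per_relapse <-
    perturb_cost(base$relapse_econ$cost_per_relapse, range)
  pv <- base$drug$price_variant
  p$drug$acquisition_cost[[pv]] <-
    perturb_cost(base$drug$acquisition_cost[[pv]], range)
  p$drug$administration_cost <-
    perturb_cost(base$drug$administration_cost, range)
  p
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` perturbed parameter sets with [draw_parameters()] and
#' evaluates all three strategies on each draw (common random parameters
#' across strategies within a draw, so shared inputs stay correlated).
#'
#' @param base A validated `natcea_params` object.
#' @param n_draws Number of Monte Carlo draws (default
#'   `base$settings$psa_draws`).
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param range Relative perturbation half-width (default
#'   `base$settings$psa_range`).
#' @param keep_parameters If `TRUE`, retain each draw's perturbed parameter
#'   set in the result.
#' @return An object of class `natcea_psa`: list with `samples` (data frame
#'   `draw`, `strategy`, `total_cost`, `total_qaly`; one row per draw and
#'   strategy), `n_draws`, `seed`, `range`, `base`, and optionally
#'   `parameters`.
#' @export
run_psa <- function(base, n_draws = base$settings$psa_draws, seed = 1L,
                    range = base$settings$psa_range, keep_parameters = FALSE) {
  validate_parameters(base)
  if (n_draws < 1) stop("n_draws must be >= 1")
  set.seed(seed)
  ns <- length(natcea_strategies)
  cost <- qaly <- matrix(NA_real_, n_draws, ns)
  kept <- if (keep_parameters) vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    pi <- tryCatch(draw_parameters(base, range = range),
                   error = function(e) stop("PSA draw ", i, " failed: ",
                                            conditionMessage(e), call. = FALSE))
    for (j in seq_len(ns)) {
      r <- run_cohort(natcea_strategies[j], pi, validate = FALSE)
      cost[i, j] <- r$total_cost
      qaly[i, j] <- r$total_qaly
    }
    if (keep_parameters) kept[[i]] <- pi
  }
  samples <- data.frame(
    draw = rep(seq_len(n_draws), each = ns),
    strategy = rep(natcea_strategies, n_draws),
    total_cost = as.vector(t(cost)),
    total_qaly = as.vector(t(qaly))
  )
  out <- list(samples = samples, n_draws = n_draws, seed = seed,
              range = range, base = base)
  if (keep_parameters) out$parameters <- kept
  structure(out, class = "natcea_psa")
}

#' Cost-effectiveness plane coordinates
#'
#' Incremental cost and QALYs of each strategy versus the reference, per
#' PSA draw — the scatter behind the cost-effectiveness plane.
#'
#' @param psa A `natcea_psa` object.
#' @param reference Reference strategy identifier.
#' @return Data frame with `draw`, `strategy`, `incremental_cost`,
#'   `incremental_qaly` for the non-reference strategies.
#' @export
ce_plane <- function(psa, reference = reference_strategy()) {
  s <- psa$samples
  ref <- s[s$strategy == reference, ]
  oth <- s[s$strategy != reference, ]
  idx <- match(oth$draw, ref$draw)
  data.frame(
    draw = oth$draw,
    strategy = oth$strategy,
    incremental_cost = oth$total_cost - ref$total_cost[idx],
    incremental_qaly = oth$total_qaly - ref$total_qaly[idx]
  )
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value on the grid and each strategy, the
#' fraction of PSA draws in which that strategy has the strictly highest
#' net monetary benefit (`wtp * QALY - cost`); exact ties share their draw
#' equally. At every grid point the probabilities sum to one across
#' strategies.
#'
#' @param psa A `natcea_psa` object (or its `samples` data frame).
#' @param wtp_grid Ascending willingness-to-pay values (GBP per QALY);
#'   defaults to £0 to £50,000 in £1,000 steps, covering both NICE
#'   thresholds discussed.
#' @return An object of class `natcea_ceac`: data frame with `wtp`,
#'   `strategy`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 50000, by = 1000)) {
  samples <- if (inherits(psa, "natcea_psa")) psa$samples else psa
  if (!nrow(samples)) stop("empty PSA sample set")
  if (is.unsorted(wtp_grid, strictly = TRUE)) stop("wtp grid must be ascending")
  strategies <- unique(samples$strategy)
  cost <- matrix(samples$total_cost, ncol = length(strategies), byrow = TRUE)
  qaly <- matrix(samples$total_qaly, ncol = length(strategies), byrow = TRUE)
  n <- nrow(cost)
  out <- lapply(wtp_grid, function(l) {
    nmb <- l * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best) # ties split equally
    data.frame(wtp = l, strategy = strategies, probability = colMeans(share))
  })
  structure(do.call(rbind, out), class = c("natcea_ceac", "data.frame"),
            row.names = seq_len(length(wtp_grid) * length(strategies)))
}

#' Probability a strategy is cost-effective at a threshold
#'
#' Convenience lookup: the CEAC value for one strategy at one
#' willingness-to-pay threshold.
#'
#' @param psa A `natcea_psa` object.
#' @param strategy Strategy identifier.
#' @param wtp Willingness-to-pay threshold (GBP per QALY).
#' @return Fraction of draws in which `strategy` has the highest net
#'   monetary benefit at `wtp`.
#' @export
probability_cost_effective <- function(psa, strategy, wtp) {
  cc <- ceac(psa, wtp_grid = wtp)
  cc$probability[cc$strategy == strategy]
}

#' Plot cost-effectiveness acceptability curves
#'
#' @param x A `natcea_ceac` object.
#' @param ... Further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.natcea_ceac <- function(x, ...) {
  wide <- stats::reshape(as.data.frame(x), idvar = "wtp",
                         timevar = "strategy", direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  graphics::matplot(wide$wtp, mat, type = "l", lty = 1, lwd = 2,
                    xlab = "Willingness to pay (GBP per QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("right", legend = sub("^probability\\.", "", colnames(wide)[-1]),
                   lty = 1, lwd = 2, col = seq_len(ncol(mat)), bty = "n")
  invisible(x)
}

#' @export
print.natcea_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %d, ±%.0f%% perturbation)\n",
              x$n_draws, x$seed, 100 * x$range))
  agg <- stats::aggregate(cbind(total_cost, total_qaly) ~ strategy,
                          data = x$samples, FUN = mean)
  print(agg)
  invisible(x)
}
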