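#' Treatment strategy identifiers
#'
#' The three natalizumab treatment strategies compared by the model, in
#' canonical order. `stop_at_conception` is the designated reference
#' strategy for all incremental analyses.
#'
#' @format Character vector of length 3.
#' @export
natcea_strategies <- c(
  "stop_at_conception",
  "stop_after_first_trimester",
  "continue_through_pregnancy"
)

#' Reference strategy for incremental analysis
#'
#' @return The identifier of the reference strategy (discontinuation of
#'   natalizumab at conception).
#' @export
reference_strategy <- function() natcea_strategies[1L]

#' Default model parameters
#'
#' Returns the complete base-case parameter set: phase schedule, annualised
#' relapse rates (ARR) per strategy and pregnancy phase, EDSS progression
#' proportions with the linear interpolation coefficients used to derive the
#' continuation value, the EDSS band structure (baseline occupancy, band
#' utilities, annual level costs), relapse economics, drug economics for the
#' originator/generic/biosimilar price variants, and economic settings
#' (discount rate, willingness-to-pay, PSA configuration).
#'
#' ARR entries are closed intervals `c(low, high)`; point values are
#' degenerate intervals. The baseline EDSS occupancy sums to 0.954; by
#' default the residual 0.046 is carried as a zero-cost, zero-utility
#' "unclassified" stratum (`edss$residual = "unclassified"`); set
#' `"renormalise"` to rescale the three bands onto the simplex instead.
#'
#' @return An object of class `natcea_params`.
#' @seealso [load_parameters()], [validate_parameters()]
#' @examples
#' p <- default_parameters()
#' p$drug$acquisition_cost[["originator"]]
#' @export
default_parameters <- function() {
  p <- list(
    schedule = list(
      pre_conception_months = 12L,
      pregnancy_months = 9L,
      post_pregnancy_months = 12L
    ),
    relapse_rates = list(
      stop_at_conception = list(
        pre_conception = c(0.29, 0.29),
        pregnancy = c(0.5, 0.6),
        post_pregnancy = c(0.4, 0.9)
      ),
      stop_after_first_trimester = list(
        pre_conception = c(0.29, 0.29),
        pregnancy = c(0.2, 0.5),
        post_pregnancy = c(0.3, 1.0)
      ),
      continue_through_pregnancy = list(
        pre_conception = c(0.21, 0.21),
        pregnancy = c(0.2, 0.2),
        post_pregnancy = c(0.2, 0.6)
      )
    ),
    progression = list(
      proportions = c(
        stop_at_conception = 0.21,
        stop_after_first_trimester = 0.16,
        continue_through_pregnancy = 0.12
      ),
      interpolation_slope = -4.58,
      interpolation_intercept = 25.63
    ),
    edss = list(
      bands = c("0-1", "2-3", "4+"),
      baseline_occupancy = c(0.539, 0.356, 0.059),
      band_utility = c(0.88, 0.75, 0.43),
      level_costs = c(488, 887, 4611, 3656, 3474, 4850, 9602, 15412, 27786, 35545),
      band_levels = list(c(0L, 1L), c(2L, 3L), 4:9),
      residual = "unclassified"
    ),
    relapse_econ = list(
      disutility_per_relapse = 0.07,
      cost_per_relapse = 1623
    ),
    drug = list(
      price_variant = "originator",
      acquisition_cost = c(originator = 1130, generic = 870, biosimilar = 666),
      administration_cost = 223,
      total_cycles = c(
        stop_at_conception = 6,
        stop_after_first_trimester = 6.75,
        continue_through_pregnancy = 8.25
      )
    ),
    settings = list(
      annual_discount_rate = 0.035,
      wtp_threshold = 20000,
      psa_draws = 1000L,
      psa_range = 0.20
    )
  )
  structure(p, class = "natcea_params")
}

#' Model horizon in months
#'
#' @param params A `natcea_params` object.
#' @return Total number of monthly cycles (33 with the default schedule).
#' @export
horizon_months <- function(params) {
  s <- params$schedule
  as.integer(s$pre_conception_months + s$pregnancy_months + s$post_pregnancy_months)
}

#' Reduce an ARR interval to its point value
#'
#' The base-case model uses the midpoint of each printed annualised relapse
#' rate interval; the surrounding uncertainty is explored by the PSA.
#'
#' @param interval Numeric `c(low, high)` with `0 <= low <= high`.
#' @return The midpoint `(low + high) / 2`.
#' @examples
#' arr_point_value(c(0.5, 0.6)) # 0.55
#' @export
arr_point_value <- function(interval) {
  stopifnot(is.numeric(interval), length(interval) == 2L)
  if (any(interval < 0) || interval[1] > interval[2]) {
    stop("invalid ARR interval: need 0 <= low <= high, got [",
         interval[1], ", ", interval[2], "]")
  }
  mean(interval)
}

#' Linear interpolation of EDSS progression proportion
#'
#' Evaluates the linear relationship `y = slope * x + intercept` (percent)
#' at a strategy index: 1 = stop at conception, 2 = stop after first
#' trimester, 3 = continue through pregnancy. With the default coefficients
#' (-4.58, 25.63) the three indices give 21.05, 16.47 and 11.89 percent,
#' matching the tabulated 21/16/12% to rounding; the model derives the
#' continuation value (index 3) this way because it is not observed
#' directly.
#'
#' @param index Strategy index in `{1, 2, 3}`.
#' @param slope,intercept Linear coefficients, percent per index and percent.
#' @return Progression proportion in percent.
#' @export
progression_linear <- function(index, slope = -4.58, intercept = 25.63) {
  if (!index %in% c(1, 2, 3)) stop("strategy index must be 1, 2 or 3")
  slope * index + intercept
}

#' Logarithmic interpolation of EDSS progression proportion
#'
#' Fits `y = a * log(x) + b` through two anchor points and evaluates it at a
#' strategy index; used by the logarithmic-progression scenario analysis as
#' an alternative to [progression_linear()].
#'
#' @param anchor1,anchor2 Numeric `c(index, percent)` anchor points with
#'   distinct positive indices.
#' @param index Positive evaluation index.
#' @return Interpolated progression proportion in percent.
#' @examples
#' progression_log(c(1, 21), c(2, 16), 3) # ~13.08
#' @export
progression_log <- function(anchor1, anchor2, index) {
  stopifnot(length(anchor1) == 2L, length(anchor2) == 2L)
  x1 <- anchor1[1]; x2 <- anchor2[1]
  if (x1 <= 0 || x2 <= 0 || index <= 0) stop("indices must be positive")
  if (x1 == x2) stop("anchor indices must be distinct")
  a <- (anchor2[2] - anchor1[2]) / (log(x2) - log(x1))
  b <- anchor1[2] - a * log(x1)
  a * log(index) + b
}

#' Annual cost per EDSS band
#'
#' Aggregates the annual per-level EDSS costs into band costs using the
#' band-to-level map in `params$edss$band_levels` (unweighted mean of the
#' member levels). The 4+ band's level range is a documented calibration
#' knob: the tabulated costs price individual EDSS levels 0-9 while the
#' cohort is tracked in three bands, and the within-band aggregation rule is
#' an assumption.
#'
#' @param params A `natcea_params` object.
#' @return Named numeric vector of annual GBP costs, one per band.
#' @export
edss_band_costs <- function(params) {
  lc <- params$edss$level_costs
  out <- vapply(params$edss$band_levels,
                function(lv) mean(lc[lv + 1L]), numeric(1))
  names(out) <- params$edss$bands
  out
}

#' Effective baseline occupancy
#'
#' Returns the band occupancy vector actually simulated: either the printed
#' values with the residual mass carried as an inert unclassified stratum
#' (default), or the printed values renormalised onto the simplex.
#'
#' @param params A `natcea_params` object.
#' @return List with `bands` (numeric per band) and `unclassified` (scalar).
#' @export
effective_occupancy <- function(params) {
  occ <- params$edss$baseline_occupancy
  if (identical(params$edss$residual, "renormalise")) {
    list(bands = occ / sum(occ), unclassified = 0)
  } else {
    list(bands = occ, unclassified = max(0, 1 - sum(occ)))
  }
}

# ---- validation -----------------------------------------------------------

#' Validate a parameter set
#'
#' Checks every structural invariant of the parameter set and reports all
#' violations at once, each with the offending field path.
#'
#' @param params A `natcea_params` object (or plain list of the same shape).
#' @return `params`, invisibly, if valid; otherwise an error listing every
#'   violated invariant.
#' @export
validate_parameters <- function(params) {
  errs <- character(0)
  bad <- function(path, msg) errs[[length(errs) + 1L]] <<- paste0(path, ": ", msg)

  s <- params$schedule
  for (f in c("pre_conception_months", "pregnancy_months", "post_pregnancy_months")) {
    v <- s[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      bad(paste0("schedule$", f), "must be a positive integer month count")
  }

  for (st in natcea_strategies) {
    ph <- params$relapse_rates[[st]]
    if (is.null(ph)) { bad(paste0("relapse_rates$", st), "missing strategy"); next }
    for (p in c("pre_conception", "pregnancy", "post_pregnancy")) {
      iv <- ph[[p]]
      path <- paste0("relapse_rates$", st, "$", p)
      if (is.null(iv) || length(iv) != 2L || !is.numeric(iv)) {
        bad(path, "must be a numeric interval c(low, high)")
      } else if (any(iv < 0) || iv[1] > iv[2]) {
        bad(path, sprintf("invalid interval [%g, %g]: need 0 <= low <= high", iv[1], iv[2]))
      }
    }
  }

  pr <- params$progression$proportions
  if (length(pr) != 3L || is.null(names(pr)) || !setequal(names(pr), natcea_strategies)) {
    bad("progression$proportions", "must name all three strategies")
  } else {
    for (st in names(pr)) {
      if (!is.finite(pr[[st]]) || pr[[st]] < 0 || pr[[st]] > 1)
        bad(paste0("progression$proportions$", st), "must lie in [0, 1]")
    }
  }

  e <- params$edss
  nb <- length(e$bands)
  if (length(e$baseline_occupancy) != nb) {
    bad("edss$baseline_occupancy", "length must match number of bands")
  } else {
    for (i in seq_len(nb)) {
      v <- e$baseline_occupancy[i]
      if (!is.finite(v) || v < 0 || v > 1)
        bad(sprintf("edss$baseline_occupancy[%d]", i), "must lie in [0, 1]")
    }
    if (sum(e$baseline_occupancy) > 1 + 1e-9)
      bad("edss$baseline_occupancy", "band occupancies must sum to at most 1")
  }
  if (length(e$band_utility) != nb) {
    bad("edss$band_utility", "length must match number of bands")
  } else {
    for (i in seq_len(nb)) {
      v <- e$band_utility[i]
      if (!is.finite(v) || v < 0 || v > 1)
        bad(sprintf("edss$band_utility[%d]", i), "utilities must lie in [0, 1]")
    }
  }
  if (any(!is.finite(e$level_costs)) || any(e$level_costs < 0))
    bad("edss$level_costs", "annual level costs must be nonnegative")
  if (length(e$band_levels) != nb) {
    bad("edss$band_levels", "need one level range per band")
  } else {
    for (i in seq_len(nb)) {
      lv <- e$band_levels[[i]]
      if (any(lv < 0) || any(lv + 1L > length(e$level_costs)))
        bad(sprintf("edss$band_levels[[%d]]", i), "level indices outside the cost ladder")
    }
  }
  if (!identical(e$residual, "unclassified") && !identical(e$residual, "renormalise"))
    bad("edss$residual", "must be 'unclassified' or 'renormalise'")

  re <- params$relapse_econ
  if (!is.finite(re$disutility_per_relapse) || re$disutility_per_relapse < 0)
    bad("relapse_econ$disutility_per_relapse", "must be >= 0")
  if (!is.finite(re$cost_per_relapse) || re$cost_per_relapse < 0)
    bad("relapse_econ$cost_per_relapse", "must be >= 0")

  d <- params$drug
  if (!d$price_variant %in% names(d$acquisition_cost))
    bad("drug$price_variant", sprintf("unknown variant '%s'", d$price_variant))
  if (any(!is.finite(d$acquisition_cost)) || any(d$acquisition_cost < 0))
    bad("drug$acquisition_cost", "must be >= 0")
  if (!is.finite(d$administration_cost) || d$administration_cost < 0)
    bad("drug$administration_cost", "must be >= 0")
  tc <- d$total_cycles
  if (length(tc) != 3L || is.null(names(tc)) || !setequal(names(tc), natcea_strategies)) {
    bad("drug$total_cycles", "must name all three strategies")
  } else if (any(tc < 0)) {
    bad("drug$total_cycles", "cycle counts must be >= 0")
  } else if (!(tc[["continue_through_pregnancy"]] >= tc[["stop_after_first_trimester"]] &&
               tc[["stop_after_first_trimester"]] >= tc[["stop_at_conception"]])) {
    bad("drug$total_cycles",
        "ordering violated: need continue >= stop_after_first_trimester >= stop_at_conception")
  }

  g <- params$settings
  if (!is.finite(g$annual_discount_rate) || g$annual_discount_rate < 0 || g$annual_discount_rate >= 1)
    bad("settings$annual_discount_rate", "must lie in [0, 1)")
  if (!is.finite(g$wtp_threshold) || g$wtp_threshold <= 0)
    bad("settings$wtp_threshold", "must be > 0")
  if (!is.finite(g$psa_draws) || g$psa_draws < 1)
    bad("settings$psa_draws", "must be >= 1")
  if (!is.finite(g$psa_range) || g$psa_range <= 0 || g$psa_range >= 1)
    bad("settings$psa_range", "must lie in (0, 1)")

  if (length(errs)) {
    stop("invalid model parameters:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(params)
}

# ---- configuration I/O ----------------------------------------------------

# deep merge: values in 'over' replace same-named values in 'base'
merge_params <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], over[[nm]])
    } else {
      v <- over[[nm]]
      b <- base[[nm]]
      if (is.list(v) && !is.null(b) && is.atomic(b)) v <- unlist(v)
      if (!is.null(b) && !is.null(names(b)) && !is.null(names(v))) {
        b[names(v)] <- v
        v <- b
      } else if (!is.null(b) && !is.null(names(b)) && is.null(names(v)) &&
                 length(v) == length(b)) {
        names(v) <- names(b) # full unnamed override keeps canonical order
      }
      base[[nm]] <- v
    }
  }
  base
}

#' Load model parameters from a YAML configuration file
#'
#' Reads a configuration file with one section per parameter block
#' (`schedule`, `relapse_rates`, `progression`, `edss`, `relapse_econ`,
#' `drug`, `settings`). Any omitted field defaults to the packaged
#' base-case value; the merged set is validated before being returned. The
#' packaged base-case configuration lives at
#' `system.file("extdata", "base_case.yaml", package = "natcea")`.
#'
#' @param path Path to a YAML configuration file, or `NULL` for the packaged
#'   base case.
#' @param edss_costs_csv Optional CSV overriding the EDSS level-cost ladder,
#'   with columns `edss_level` (0-9) and `annual_cost_gbp`.
#' @return A validated `natcea_params` object.
#' @export
load_parameters <- function(path = NULL, edss_costs_csv = NULL) {
  base <- default_parameters()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    over <- yaml::read_yaml(path)
    if (!is.list(over)) stop("malformed configuration: top level must be a mapping")
    unknown <- setdiff(names(over), names(base))
    if (length(unknown))
      stop("unknown configuration section(s): ", paste(unknown, collapse = ", "))
    base <- merge_params(base, over)
  }
  if (!is.null(edss_costs_csv)) {
    tab <- utils::read.csv(edss_costs_csv)
    if (!all(c("edss_level", "annual_cost_gbp") %in% names(tab)))
      stop("EDSS cost table needs columns edss_level, annual_cost_gbp")
    lc <- base$edss$level_costs
    lc[tab$edss_level + 1L] <- tab$annual_cost_gbp
    base$edss$level_costs <- lc
  }
  base$schedule <- lapply(base$schedule, as.integer)
  base <- structure(base, class = "natcea_params")
  validate_parameters(base)
  base
}

#' Write a parameter set to a YAML configuration file
#'
#' Emits the canonical configuration dump of a parameter set, suitable for
#' provenance logging and for reloading with [load_parameters()]
#' (round-trip safe).
#'
#' @param params A `natcea_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  # named atomic vectors become YAML maps so their names survive a round trip
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(unclass(params)), path, precision = 15L)
  invisible(path)
}

#' @export
print.natcea_params <- function(x, ...) {
  cat("Markov cohort model parameters (natcea)\n")
  cat(sprintf("  horizon: %d monthly cycles (%d pre-conception + %d pregnancy + %d post-pregnancy)\n",
              horizon_months(x), x$schedule$pre_conception_months,
              x$schedule$pregnancy_months, x$schedule$post_pregnancy_months))
  cat(sprintf("  price variant: %s (acquisition £%g + administration £%g per cycle)\n",
              x$drug$price_variant,
              x$drug$acquisition_cost[[x$drug$price_variant]],
              x$drug$administration_cost))
  cat(sprintf("  discount rate: %.1f%%/yr; WTP £%g/QALY; PSA %d draws at ±%.0f%%\n",
              100 * x$settings$annual_discount_rate, x$settings$wtp_threshold,
              x$settings$psa_draws, 100 * x$settings$psa_range))
  cat(sprintf("  EDSS residual handling: %s\n", x$edss$residual))
  invisible(x)
}
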