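#' Define a scenario
#'
#' A scenario names a drug price variant, a progression interpolation
#' function, a willingness-to-pay threshold and optional parameter
#' overrides, to be applied on top of a base parameter set by
#' [run_scenario()].
#'
#' @param name Unique scenario label.
#' @param price_variant One of `"originator"`, `"generic"`, `"biosimilar"`.
#' @param progression `"linear"` (base case) or `"logarithmic"`.
#' @param wtp Willingness-to-pay threshold (GBP per QALY).
#' @param overrides Optional named list of parameter patches, merged onto
#'   the base set (same nesting as the parameter object).
#' @return An object of class `natcea_scenario_spec`.
#' @export
scenario_spec <- function(name, price_variant = "originator",
                          progression = c("linear", "logarithmic"),
                          wtp = 20000, overrides = list()) {
  progression <- match.arg(progression)
  if (!price_variant %in% c("originator", "generic", "biosimilar"))
    stop("unknown price variant: ", price_variant)
  structure(list(name = name, price_variant = price_variant,
                 progression = progression, wtp = wtp, overrides = overrides),
            class = "natcea_scenario_spec")
}

#' The five standard analyses
#'
#' Base case (originator prices, linear progression, £20,000/QALY), the
#' generic and biosimilar price variants, the logarithmic-progression
#' variant, and the £30,000/QALY threshold variant.
#'
#' @return Named list of `natcea_scenario_spec`.
#' @export
standard_scenarios <- function() {
  specs <- list(
    scenario_spec("base_case"),
    scenario_spec("generic_price", price_variant = "generic"),
    scenario_spec("biosimilar_price", price_variant = "biosimilar"),
    scenario_spec("log_progression", progression = "logarithmic"),
    scenario_spec("wtp_30000", wtp = 30000)
  )
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

# resolve a scenario's full parameter set
scenario_parameters <- function(spec, base = default_parameters()) {
  p <- base
  p$drug$price_variant <- spec$price_variant
  if (spec$progression == "logarithmic") {
    # anchor on the two observed strategies (indices 1 and 2, in percent)
    # and re-derive only the continuation proportion, mirroring how the
    # linear base case obtained it
    pr <- p$progression$proportions
    p$progression$proportions[["continue_through_pregnancy"]] <-
      progression_log(c(1, 100 * pr[["stop_at_conception"]]),
                      c(2, 100 * pr[["stop_after_first_trimester"]]),
                      3) / 100
  }
  p$settings$wtp_threshold <- spec$wtp
  if (length(spec$overrides)) p <- merge_params(p, spec$overrides)
  p <- structure(p, class = "natcea_params")
  validate_parameters(p)
  p
}

#' Run one scenario
#'
#' Applies the scenario's price variant, progression function and overrides
#' to the base parameters, runs all three strategies deterministically, and
#' computes incrementals versus the stop-at-conception reference at the
#' scenario's willingness-to-pay threshold.
#'
#' @param spec A `natcea_scenario_spec`.
#' @param base A `natcea_params` object to start from.
#' @return An object of class `natcea_scenario`: list with `spec`, the
#'   resolved `params`, `results` (named list of `natcea_result`),
#'   `totals` (costs/QALYs table) and `incrementals` (incremental table,
#'   reference row `NA`).
#' @export
run_scenario <- function(spec, base = default_parameters()) {
  params <- scenario_parameters(spec, base)
  res <- run_strategies(params)
  structure(list(
    spec = spec,
    params = params,
    results = res,
    totals = results_table(res),
    incrementals = incremental_table(res, wtp = spec$wtp)
  ), class = "natcea_scenario")
}

#' Run a manifest of scenarios
#'
#' @param specs List of `natcea_scenario_spec` (default: the five named
#'   analyses from [standard_scenarios()]).
#' @param base A `natcea_params` object to start from.
#' @return Named list of `natcea_scenario` plus a combined `summary` data
#'   frame (attribute-free long table: scenario, strategy, totals and
#'   incrementals).
#' @export
run_all_scenarios <- function(specs = standard_scenarios(),
                              base = default_parameters()) {
  nms <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("scenario names must be unique")
  runs <- lapply(specs, run_scenario, base = base)
  names(runs) <- nms
  summary <- do.call(rbind, lapply(runs, function(r) {
    cbind(scenario = r$spec$name,
          merge(r$totals, r$incrementals, by = "strategy", sort = FALSE))
  }))
  rownames(summary) <- NULL
  list(scenarios = runs, summary = summary)
}

#' @export
print.natcea_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s prices, %s progression, WTP £%g/QALY)\n",
              x$spec$name, x$spec$price_variant, x$spec$progression, x$spec$wtp))
  print(render_results(x$totals, x$incrementals))
  invisible(x)
}
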