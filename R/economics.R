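#' Net monetary benefit
#'
#' `nmb = wtp * delta_qaly - delta_cost`: the monetary value of the health
#' gain at willingness-to-pay `wtp`, net of the additional cost. A positive
#' value means the strategy is cost-effective versus its reference at that
#' threshold.
#'
#' @param delta_cost Incremental cost (GBP).
#' @param delta_qaly Incremental QALYs.
#' @param wtp Willingness-to-pay threshold (GBP per QALY).
#' @return Net monetary benefit in GBP.
#' @export
net_monetary_benefit <- function(delta_cost, delta_qaly, wtp) {
  wtp * delta_qaly - delta_cost
}

classify_dominance <- function(delta_cost, delta_qaly) {
  if (delta_cost == 0 && delta_qaly == 0) return("equivalent")
  if (delta_cost <= 0 && delta_qaly >= 0) return("dominant")
  if (delta_cost >= 0 && delta_qaly <= 0) return("dominated")
  "trade_off"
}

#' Incremental cost-effectiveness statistics for one strategy pair
#'
#' Computes the incremental cost (ΔC) and incremental QALYs (ΔE) of a
#' strategy versus a reference, the ICER (ΔC/ΔE, undefined when ΔE = 0),
#' the net monetary benefit at the willingness-to-pay threshold, and the
#' dominance classification.
#'
#' @param result,reference `natcea_result` objects computed under identical
#'   economic settings.
#' @param wtp Willingness-to-pay threshold (GBP per QALY); defaults to the
#'   threshold the results were run with.
#' @return An object of class `natcea_incremental`: list with `strategy`,
#'   `reference`, `delta_cost`, `delta_qaly`, `icer` (`NA` when ΔE = 0),
#'   `nmb`, `wtp`, `dominance`.
#' @export
compute_incremental <- function(result, reference,
                                wtp = result$settings$wtp_threshold) {
  if (!identical(result$settings$annual_discount_rate,
                 reference$settings$annual_discount_rate))
    stop("results were computed under different discount rates")
  if (!is.numeric(wtp) || wtp <= 0) stop("wtp must be > 0")
  dC <- result$total_cost - reference$total_cost
  dE <- result$total_qaly - reference$total_qaly
  structure(list(
    strategy = result$strategy,
    reference = reference$strategy,
    delta_cost = dC,
    delta_qaly = dE,
    icer = if (dE == 0) NA_real_ else dC / dE,
    nmb = net_monetary_benefit(dC, dE, wtp),
    wtp = wtp,
    dominance = classify_dominance(dC, dE)
  ), class = "natcea_incremental")
}

#' Willingness-to-pay decision rule
#'
#' A strategy is cost-effective versus its reference iff its net monetary
#' benefit at the threshold is strictly positive (`wtp * ΔE - ΔC > 0`),
#' which for ΔE > 0 is equivalent to ICER < wtp. Dominant results are
#' always cost-effective, dominated ones never.
#'
#' @param incremental A `natcea_incremental` object.
#' @param wtp Threshold to decide at; defaults to the one stored in
#'   `incremental`.
#' @return Logical.
#' @export
cost_effective <- function(incremental, wtp = incremental$wtp) {
  if (incremental$dominance == "dominant") return(TRUE)
  if (incremental$dominance == "dominated") return(FALSE)
  net_monetary_benefit(incremental$delta_cost, incremental$delta_qaly, wtp) > 0
}

#' @export
print.natcea_incremental <- function(x, ...) {
  cat(sprintf("%s vs %s: ΔC = £%.0f, ΔE = %.4f QALY\n",
              x$strategy, x$reference, x$delta_cost, x$delta_qaly))
  cat(sprintf("  ICER = %s, NMB(£%g/QALY) = £%.0f [%s]\n",
              if (is.na(x$icer)) "undefined" else sprintf("£%.0f/QALY", x$icer),
              x$wtp, x$nmb, x$dominance))
  invisible(x)
}

#' Results table (total costs and QALYs per strategy)
#'
#' @param results Named list of `natcea_result` (see [run_strategies()]).
#' @return Data frame with one row per strategy: `strategy`, `total_cost`,
#'   `total_qaly` (unrounded).
#' @export
results_table <- function(results) {
  data.frame(
    strategy = vapply(results, `[[`, character(1), "strategy"),
    total_cost = vapply(results, `[[`, numeric(1), "total_cost"),
    total_qaly = vapply(results, `[[`, numeric(1), "total_qaly"),
    row.names = NULL
  )
}

#' Incremental table versus the reference strategy
#'
#' One row per strategy in canonical order; the reference row carries `NA`
#' in the incremental columns (rendered as dashes in printed output).
#'
#' @param results Named list of `natcea_result`.
#' @param reference Reference strategy identifier.
#' @param wtp Willingness-to-pay threshold (GBP per QALY).
#' @return Data frame with columns `strategy`, `delta_cost`, `delta_qaly`,
#'   `icer`, `nmb`, `dominance`.
#' @export
incremental_table <- function(results, reference = reference_strategy(),
                              wtp = results[[1]]$settings$wtp_threshold) {
  ref <- results[[reference]]
  rows <- lapply(names(results), function(s) {
    if (s == reference) {
      data.frame(strategy = s, delta_cost = NA_real_, delta_qaly = NA_real_,
                 icer = NA_real_, nmb = NA_real_, dominance = NA_character_)
    } else {
      inc <- compute_incremental(results[[s]], ref, wtp = wtp)
      data.frame(strategy = s, delta_cost = inc$delta_cost,
                 delta_qaly = inc$delta_qaly, icer = inc$icer,
                 nmb = inc$nmb, dominance = inc$dominance)
    }
  })
  do.call(rbind, rows)
}
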