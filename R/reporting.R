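# rounding only at render time: costs to whole GBP, QALYs to 2 dp, ICER to
# whole GBP, probabilities to 3 dp; machine-readable CSVs stay unrounded.

fmt_gbp <- function(x) ifelse(is.na(x), "-",
                              format(round(x), big.mark = ",", trim = TRUE))
fmt_qaly <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))

#' Human-readable rendering of the results tables
#'
#' @param totals Data frame from [results_table()].
#' @param incrementals Optional data frame from [incremental_table()].
#' @return Data frame of formatted strings (reference cells as dashes).
#' @export
render_results <- function(totals, incrementals = NULL) {
  out <- data.frame(
    strategy = totals$strategy,
    `total cost (£)` = fmt_gbp(totals$total_cost),
    `total QALYs` = fmt_qaly(totals$total_qaly),
    check.names = FALSE
  )
  if (!is.null(incrementals)) {
    m <- match(totals$strategy, incrementals$strategy)
    out$`ΔC (£)` <- fmt_gbp(incrementals$delta_cost[m])
    out$`ΔE (QALY)` <- fmt_qaly(incrementals$delta_qaly[m])
    out$ICER <- fmt_gbp(incrementals$icer[m])
    out$`NMB (£)` <- fmt_gbp(incrementals$nmb[m])
  }
  out
}

#' Write a machine-readable results CSV
#'
#' Unrounded values, no thousands separators; reference-row incremental
#' cells are empty.
#'
#' @param df Any results data frame (totals, incrementals, CEAC, CE plane).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write every table for a scenario run
#'
#' Emits `<name>_totals.csv`, `<name>_incrementals.csv` and the resolved
#' parameter dump `<name>_params.yaml` into a directory.
#'
#' @param scenario A `natcea_scenario` object.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_scenario_outputs <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, scenario$spec$name)
  paths <- c(
    write_results_csv(scenario$totals, paste0(stem, "_totals.csv")),
    write_results_csv(scenario$incrementals, paste0(stem, "_incrementals.csv")),
    write_parameters(scenario$params, paste0(stem, "_params.yaml"))
  )
  invisible(paths)
}
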