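# Orchestration: score -> count -> regional means -> Theil series and
# decomposition -> GM(1,1) forecast, collected into one report object.

#' Regional mean efficiency table
#'
#' Arithmetic mean score of the member units of each group, per year, with
#' a trailing period average (the mean of the yearly group means) and an
#' `all` row for the full cross-section. Infeasible (NA) cells are dropped
#' from the means.
#'
#' @param eff an [efficiency_panel()].
#' @param partition a [region_partition()] covering every unit.
#' @return data frame: one row per group plus `all`; one column per year
#'   plus `average`.
#' @export
regional_means <- function(eff, partition) {
  stopifnot(inherits(eff, "efficiency_panel"))
  g <- partition_groups(partition, eff$unit_ids)
  groups <- partition$group_names
  tab <- t(vapply(groups, function(p)
    colMeans(eff$scores[g == p, , drop = FALSE], na.rm = TRUE),
    numeric(length(eff$years))))
  tab <- rbind(tab, all = colMeans(eff$scores, na.rm = TRUE))
  out <- data.frame(region = rownames(tab), tab, check.names = FALSE,
                    row.names = NULL)
  names(out)[-1] <- as.character(eff$years)
  out$average <- rowMeans(tab)
  out
}

#' Run the full efficiency-difference analysis
#'
#' Produces one report covering every stage: per-year efficient-unit
#' counts and the all-years intersection, regional mean efficiencies, the
#' annual Theil index with its within/between decomposition, and a GM(1,1)
#' forecast of the Theil trend.
#'
#' Two entry points are supported. From raw indicators (`panel`), the DEA
#' stage is run first ([evaluate_panel()]). From an already-scored
#' efficiency panel (`efficiency`), the DEA stage is skipped; this is the
#' mode that reproduces the published downstream tables, because the
#' published raw yearbook data is not deposited while the published
#' efficiency panel is. `fixtures = TRUE` is shorthand for running from the
#' bundled published panel; in that mode the forecast stage is fitted on
#' the bundled published Theil series (as in the original analysis) rather
#' than on the recomputed one.
#'
#' @param panel an [indicator_panel()] of raw indicators, or `NULL`.
#' @param efficiency an [efficiency_panel()], or `NULL`.
#' @param partition a [region_partition()]; default the builtin
#'   three-region division.
#' @param opts DEA [solve_options()] (only used with `panel`).
#' @param horizon forecast steps (>= 1).
#' @param fixtures run from the bundled published efficiency panel.
#' @return object of class `effidiff_report`: `efficiency` (the panel
#'   used), `efficient_counts` (per-year data frame), `always_efficient`,
#'   `regional_means`, `theil` (see [theil_series()]), `gm` (the fitted
#'   [fit_gm11()] model), `forecast` (data frame), `decline_pct` (relative
#'   decline, in percent, of the final forecast against the last observed
#'   index) and `meta`.
#' @export
run_full_analysis <- function(panel = NULL, efficiency = NULL,
                              partition = china_three_region(),
                              opts = solve_options(), horizon = 10,
                              fixtures = FALSE) {
  if (fixtures) {
    if (!is.null(panel) || !is.null(efficiency))
      stop("fixtures = TRUE replaces the panel/efficiency inputs")
    efficiency <- load_fixture("table1_efficiency_panel")
  }
  if (!is.null(panel) && !is.null(efficiency))
    stop("give either raw indicators or an efficiency panel, not both")
  if (is.null(panel) && is.null(efficiency))
    stop("give an indicator panel, an efficiency panel, or fixtures = TRUE")
  if (!is.null(panel)) efficiency <- evaluate_panel(panel, opts)

  counts <- data.frame(
    year = efficiency$years,
    efficient = vapply(efficiency$years, function(y)
      count_efficient(efficiency, y)$count, numeric(1)))
  always <- count_efficient(efficiency, intersection = TRUE)

  rmeans <- regional_means(efficiency, partition)
  ts <- theil_series(efficiency, partition)

  gm_input <- if (fixtures) load_fixture("table4_theil_series") else
    stats::setNames(ts$table$theil, ts$table$year)
  gm <- fit_gm11(gm_input)
  fc <- predict(gm, horizon = horizon)
  last_obs <- gm_input[length(gm_input)]
  decline <- 100 * (last_obs - fc$value[nrow(fc)]) / last_obs

  structure(list(
    efficiency = efficiency,
    efficient_counts = counts,
    always_efficient = always,
    regional_means = rmeans,
    theil = ts,
    gm = gm,
    forecast = fc,
    decline_pct = unname(decline),
    meta = list(mode = if (fixtures) "fixtures" else
                  if (is.null(panel)) "efficiency" else "indicators",
                horizon = horizon, options = opts,
                version = as.character(utils::packageVersion("effidiff")))),
    class = "effidiff_report")
}

#' @export
print.effidiff_report <- function(x, ...) {
  cat("== efficiency-difference analysis report (mode:", x$meta$mode, ") ==\n")
  print(x$efficiency)
  cat("\nefficient units per year:\n")
  print(x$efficient_counts, row.names = FALSE)
  cat("\nconsistently efficient:",
      paste(x$always_efficient$units, collapse = ", "), "\n")
  cat("\nregional mean efficiency (3 d.p.):\n")
  rm3 <- x$regional_means
  rm3[-1] <- round(rm3[-1], 3)
  print(rm3, row.names = FALSE)
  cat("\nTheil index and decomposition shares (index 4 d.p., shares % 1 d.p.):\n")
  tt <- x$theil$table
  tt$theil <- round(tt$theil, 4)
  tt[-(1:2)] <- round(tt[-(1:2)], 1)
  print(tt, row.names = FALSE)
  cat("\n")
  print(x$gm)
  cat("forecast (4 d.p.):\n")
  fc <- x$forecast
  fc$value <- round(fc$value, 4)
  print(fc, row.names = FALSE)
  cat(sprintf("\nrelative decline of the final forecast vs last observed: %.2f%%\n",
              x$decline_pct))
  invisible(x)
}

#' Write all report tables as delimited text files
#'
#' Emits `efficiency.csv` (long layout), `efficient_counts.csv`,
#' `regional_means.csv`, `theil_decomposition.csv`, `forecast.csv` and a
#' machine-readable `run_metadata.dcf`.
#'
#' @param report an [run_full_analysis()] report.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "effidiff_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_efficiency_panel(report$efficiency, file.path(dir, "efficiency.csv"))
  utils::write.csv(report$efficient_counts,
                   file.path(dir, "efficient_counts.csv"), row.names = FALSE)
  utils::write.csv(report$regional_means,
                   file.path(dir, "regional_means.csv"), row.names = FALSE)
  utils::write.csv(report$theil$table,
                   file.path(dir, "theil_decomposition.csv"),
                   row.names = FALSE)
  utils::write.csv(report$forecast, file.path(dir, "forecast.csv"),
                   row.names = FALSE)
  meta <- c(mode = report$meta$mode, horizon = report$meta$horizon,
            version = report$meta$version,
            gm_a = report$gm$a, gm_b = report$gm$b,
            mean_relative_error = report$gm$mean_relative_error,
            decline_pct = report$decline_pct)
  write.dcf(as.data.frame(t(meta)), file.path(dir, "run_metadata.dcf"))
  invisible(dir)
}
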