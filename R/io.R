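# Results I/O: long-format CSV, JSON summaries, an outcome table shaped like
# the published projection table, and a simple observed-vs-simulated plot.

#' Write simulation results
#'
#' Writes the annual indicator series as long-format CSV
#' (`year, scenario, outcome, age, sex, value`; aggregate indicators carry
#' `NA` age/sex) and, when `"json"` is requested, a JSON summary including the
#' scenario metadata.
#'
#' @param result a `cvdsim_result`.
#' @param path output path without extension (`.csv` / `.json` appended).
#' @param format subset of `c("csv", "json")`.
#' @return the paths written, invisibly.
#' @export
write_results <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  df <- as.data.frame(result)
  outcome_cols <- setdiff(names(df), "year")
  long <- do.call(rbind, lapply(outcome_cols, function(oc) {
    data.frame(year = df$year, scenario = attr(result, "scenario"),
               outcome = oc, age = NA_integer_, sex = NA_character_,
               value = df[[oc]])
  }))
  long <- long[order(long$year, long$outcome), ]
  if (nrow(df) == 0L) warning("empty horizon: writing header-only file", call. = FALSE)
  paths <- character(0)
  if ("csv" %in% format) {
    p <- paste0(path, ".csv")
    utils::write.csv(long, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if ("json" %in% format) {
    p <- paste0(path, ".json")
    jsonlite::write_json(list(scenario = attr(result, "scenario"),
                              years = df$year,
                              series = as.list(df[outcome_cols])),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a results CSV
#'
#' @param path a CSV written by [write_results()].
#' @return a wide data.frame of the aggregate annual series.
#' @export
read_results_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  long <- long[is.na(long$age), ]
  wide <- stats::reshape(long[, c("year", "outcome", "value")],
                         idvar = "year", timevar = "outcome", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide[order(wide$year), ]
}

#' Outcome projection table
#'
#' A table of the four headline outcomes (CVD events, CVD deaths, post-CVD
#' population, age-adjusted incidence rate) at selected years, with the
#' percent change over the horizon and, for non-base scenarios, the percent
#' reduction versus base at the final year. When a sensitivity summary is
#' supplied its percentile interval is appended to each cell.
#'
#' @param results named list of `cvdsim_result`s; must include `base`.
#' @param years report years (default 2010/2020/2030/2040).
#' @param intervals optional named list of [run_sensitivity()] outputs,
#'   parallel to `results`.
#' @return a data.frame of class `cvdsim_table` (printed as markdown-ish
#'   text); columns: scenario, outcome, one per report year, `pct_change`,
#'   `reduction_vs_base`.
#' @export
report_table <- function(results, years = c(2010, 2020, 2030, 2040),
                         intervals = NULL) {
  stopifnot("base" %in% names(results))
  outcomes <- c(events = "CVD Events", cvd_deaths = "CVD Deaths",
                post_cvd = "Post-CVD Population",
                age_adjusted_incidence = "Age-Adjusted Incidence Rate")
  rows <- list()
  for (sc in names(results)) {
    res <- results[[sc]]
    red <- if (sc == "base") rep(NA_real_, length(outcomes)) else
      compare_scenarios(res, results$base, year = max(res$year),
                        outcomes = names(outcomes))
    for (j in seq_along(outcomes)) {
      oc <- names(outcomes)[j]
      cells <- vapply(years, function(y) {
        v <- res[[oc]][match(y, res$year)]
        fmt_cell(v, interval_for(intervals, sc, y, oc), oc)
      }, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc, outcome = outcomes[[j]],
        t(stats::setNames(cells, paste0("y", years))),
        pct_change = round(pct_change(res, oc), 1),
        reduction_vs_base = round(red[[j]], 1),
        check.names = FALSE
      )
    }
  }
  structure(do.call(rbind, rows), class = c("cvdsim_table", "data.frame"))
}

interval_for <- function(intervals, sc, year, outcome) {
  if (is.null(intervals) || is.null(intervals[[sc]])) return(NULL)
  s <- intervals[[sc]]
  i <- s$year == year & s$outcome == outcome
  if (!any(i)) return(NULL)
  c(s$lower[i][1], s$upper[i][1])
}

fmt_cell <- function(v, ci, outcome) {
  fmt1 <- function(x) {
    if (outcome == "age_adjusted_incidence") sprintf("%.3f%%", 100 * x)
    else format(round(x), big.mark = ",", scientific = FALSE)
  }
  if (is.null(ci)) fmt1(v)
  else sprintf("%s (%s-%s)", fmt1(v), fmt1(ci[1]), fmt1(ci[2]))
}

#' @export
print.cvdsim_table <- function(x, ...) {
  df <- as.data.frame(x)
  cat(paste(names(df), collapse = " | "), "\n")
  cat(paste(rep("---", ncol(df)), collapse = " | "), "\n")
  for (i in seq_len(nrow(df))) {
    cat(paste(vapply(df[i, ], as.character, character(1)), collapse = " | "), "\n")
  }
  invisible(x)
}

#' Observed-versus-simulated validation plot
#'
#' Plots each observed target series against the corresponding simulated
#' series (base graphics), one panel per series.
#'
#' @param targets a `calibration_targets`.
#' @param result a `cvdsim_result`.
#' @return `NULL`, invisibly.
#' @export
plot_observed_vs_simulated <- function(targets, result) {
  series <- colnames(targets$prevalence)
  np <- length(series) + as.integer(length(targets$total_events) > 0)
  old <- graphics::par(mfrow = c(1, np)); on.exit(graphics::par(old))
  sim_prev <- cbind(diabetes = result$prev_diabetes,
                    hypertension = result$prev_hypertension,
                    smoking = result$prev_smoking)
  for (f in series) {
    yrs <- as.integer(rownames(targets$prevalence))
    graphics::plot(yrs, targets$prevalence[, f], pch = 16,
                   xlab = "year", ylab = "prevalence", main = f,
                   ylim = range(c(targets$prevalence[, f],
                                  sim_prev[match(yrs, result$year), f]), na.rm = TRUE))
    graphics::lines(result$year, sim_prev[, f], col = "steelblue", lwd = 2)
  }
  if (length(targets$total_events)) {
    yrs <- as.integer(names(targets$total_events))
    graphics::plot(yrs, targets$total_events, pch = 16, xlab = "year",
                   ylab = "events/yr", main = "CVD events",
                   ylim = range(c(targets$total_events, result$events)))
    graphics::lines(result$year, result$events, col = "firebrick", lwd = 2)
  }
  invisible(NULL)
}
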