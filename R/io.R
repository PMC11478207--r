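#' Read a voltage trace from CSV
#'
#' Canonical dialect: header `time_ms,voltage_mV`, comma-separated,
#' decimal point. Loggers exporting seconds are handled by
#' `time_unit = "s"` (times are converted to ms on read). The time
#' column must be strictly increasing and uniformly sampled (each
#' interval within 1% of the median interval).
#'
#' @param path CSV file path.
#' @param time_unit `"ms"` (default) or `"s"`.
#' @param delimiter field separator (default `","`).
#' @param header does the file carry a header row (default TRUE)?
#' @return A [trace()] with `dt` = median inter-sample interval and
#'   `t0` = first time (may be negative).
#' @export
read_trace_csv <- function(path, time_unit = c("ms", "s"),
                           delimiter = ",", header = TRUE) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = header, sep = delimiter,
                          colClasses = "numeric")
  if (ncol(df) < 2L) stop("expected 2 columns (time, voltage) in ", path)
  tt <- df[[1]]
  v <- df[[2]]
  if (any(!is.finite(tt)) || any(!is.finite(v)))
    stop("non-finite cells in ", path)
  if (time_unit == "s") tt <- tt * 1000
  d <- diff(tt)
  if (any(d <= 0)) stop("time must be strictly increasing in ", path)
  dt <- stats::median(d)
  if (any(abs(d - dt) > 0.01 * dt))
    stop("non-uniform sampling in ", path,
         " (intervals deviate > 1% from the median ", dt, " ms)")
  trace(v, dt, t0 = tt[1])
}

#' Write a trace to CSV
#'
#' Canonical dialect `time_ms,voltage_mV`, one row per sample.
#'
#' @param trace a [trace()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# flat named list mirroring the report's table rows
report_to_list <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  list(
    input = list(mean_mV = report$input_stats$mean,
                 sd_mV = report$input_stats$sd,
                 max_mV = report$input_stats$max,
                 min_mV = report$input_stats$min,
                 n = report$input_stats$n),
    output = list(mean_mV = report$output_stats$mean,
                  sd_mV = report$output_stats$sd,
                  max_mV = report$output_stats$max,
                  min_mV = report$output_stats$min,
                  n = report$output_stats$n),
    delta_mean_mV = report$delta_mean,
    cv = list(input_pct = report$cv_input, output_pct = report$cv_output),
    snr = list(input_db = report$snr_input_db,
               output_db = report$snr_output_db,
               gain_db = report$snr_gain_db),
    correlation = report$r,
    rmse_mV = report$rmse,
    max_diff_mV = report$max_diff,
    max_diff_time_ms = report$max_diff_time,
    lag_ms = report$lag_ms,
    lag_samples = report$lag_samples,
    ks_D = report$ks$D,
    ks_p = report$ks$p,
    ks_H = report$ks$H
  )
}

#' Serialise a comparison report to JSON
#'
#' Field names mirror the summary-table rows (`mean_mV`, `sd_mV`,
#' `max_mV`, `min_mV`, `correlation`, `rmse_mV`, `max_diff_mV`,
#' `max_diff_time_ms`, `lag_ms`, `lag_samples`, `ks_D`, `ks_p`, `ks_H`)
#' plus `cv` and `snr` blocks. Numbers are written at full precision.
#'
#' @param report a [compare()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Render a comparison report as an aligned text table
#'
#' Three blocks mirroring the per-mode summary tables: input/output
#' descriptive statistics, comparative metrics, and the
#' Kolmogorov-Smirnov test.
#'
#' @param report a [compare()] result.
#' @return Character vector of lines.
#' @export
render_report_text <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  f <- function(x, d = 4) formatC(x, digits = d, format = "f")
  row <- function(m, a, b) sprintf("%-28s %12s %12s", m, a, b)
  c(
    "Input/Output statistics",
    row("Metric", "Input", "Output"),
    row("Mean (mV)", f(report$input_stats$mean, 2), f(report$output_stats$mean, 2)),
    row("Standard deviation (mV)", f(report$input_stats$sd, 2), f(report$output_stats$sd, 2)),
    row("Maximum (mV)", f(report$input_stats$max, 2), f(report$output_stats$max, 2)),
    row("Minimum (mV)", f(report$input_stats$min, 2), f(report$output_stats$min, 2)),
    "",
    "Comparative Metrics",
    sprintf("%-28s %12s", "Correlation coefficient", f(report$r)),
    sprintf("%-28s %12s", "Root mean square error (mV)", f(report$rmse)),
    sprintf("%-28s %s", "Maximum difference (mV)",
            paste0(f(report$max_diff, 2), " at ", f(report$max_diff_time, 2), " ms")),
    sprintf("%-28s %12s", "Time lag (ms)", f(report$lag_ms, 0)),
    sprintf("%-28s %12s", "Time lag (samples)", f(report$lag_samples, 0)),
    sprintf("%-28s %12s", "SNR gain (dB)", f(report$snr_gain_db, 2)),
    "",
    "Kolmogorov-Smirnov Test",
    sprintf("%-28s %12s", "H-value", as.integer(report$ks$H)),
    sprintf("%-28s %12s", "p-value",
            if (report$ks$p < 1e-4) "<0.0001" else f(report$ks$p)),
    sprintf("%-28s %12s", "KS statistic", f(report$ks$D))
  )
}
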