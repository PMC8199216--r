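#' Write an analysis report to CSV or JSON
#'
#' Serializes occupancy reports, group statistics, score comparisons,
#' dose-response fits, heat maps and RMSD traces. Numbers are written
#' in full precision (UTF-8, "." decimal separator) so that reading the
#' file back reproduces every numeric field to at least 6 significant
#' digits. JSON reports carry the detection cutoffs actually used when
#' the object holds them.
#'
#' @param report the report object.
#' @param path output file path.
#' @param format `"csv"` or `"json"` (default: by file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path,
                         format = if (grepl("\\.json$", path, TRUE)) "json" else "csv") {
  format <- match.arg(format, c("csv", "json"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, mode = 2L) != 0L)
    stop_input("write_report: cannot write to %s", path)
  df <- report_as_df(report)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = TRUE)
  } else {
    payload <- list(rows = df)
    spec <- attr(report, "spec", exact = TRUE)
    if (!is.null(spec)) payload$cutoffs <- unclass(spec)
    if (inherits(report, "fit_4pl"))
      payload <- c(payload,
                   list(coefficients = as.list(report$coefficients),
                        se = as.list(report$se),
                        converged = report$converged,
                        init = as.list(report$init)))
    gap <- attr(report, "gap", exact = TRUE)
    if (!is.null(gap)) payload$gap <- gap
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", dataframe = "rows")
  }
  invisible(path)
}

report_as_df <- function(report) {
  if (inherits(report, "occupancy_heatmap")) {
    m <- unclass(report)
    return(cbind(data.frame(compound = rownames(m), stringsAsFactors = FALSE),
                 as.data.frame(m, check.names = FALSE)))
  }
  if (inherits(report, "rmsd_trace"))
    return(data.frame(frame = seq_along(report), rmsd = as.numeric(report)))
  if (inherits(report, "fit_4pl")) {
    co <- report$coefficients
    return(data.frame(parameter = names(co), estimate = as.numeric(co),
                      std_error = as.numeric(report$se[names(co)]),
                      stringsAsFactors = FALSE))
  }
  if (inherits(report, "separation"))
    return(data.frame(threshold = report$threshold,
                      misclassified = report$misclassified,
                      overlap = report$overlap,
                      direction = report$direction, n = report$n))
  if (is.data.frame(report)) return(as.data.frame(report))
  stop_input("write_report: cannot serialize an object of class %s",
             paste(class(report), collapse = "/"))
}

#' Read back a CSV report
#'
#' Thin wrapper around `read.csv` with the settings matching
#' [write_report()]; used for round-trip checks and downstream reuse.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_report_csv <- function(path) {
  if (!file.exists(path)) stop_input("read_report_csv: no such file: %s", path)
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                  stringsAsFactors = FALSE)
}
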