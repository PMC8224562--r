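## Result-report serialization. Every report type has a canonical tabular
## (CSV) and structured (JSON) form; round-tripping reproduces the table to
## at least 6 significant digits (numbers are written at full precision).

#' Write a result report to CSV or JSON
#'
#' Supported report types: `specialty_table`, `classification_report`,
#' `corpus_stats`, `cluster_model`, plain data frames. Reading the written
#' file back with [read_report()] reproduces the table to at least 6
#' significant digits.
#'
#' @param report the result object.
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- as.data.frame(report)
  if (format == "csv") {
    data.table::fwrite(df, path, bom = FALSE)
  } else {
    payload <- if (inherits(report, "classification_report")) {
      list(classifier = report$classifier, folds = report$folds,
           per_class = report$per_class, macro = as.list(report$macro),
           confusion = as.data.frame.table(report$confusion,
                                           responseName = "count"))
    } else df
    jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return a data frame (CSV) or list/data frame (JSON).
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    as.data.frame(data.table::fread(path, encoding = "UTF-8"))
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
}
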