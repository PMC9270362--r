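REPORT_COLUMNS <- c("Precursor.Id", "Run", "Score", "Q.Value", "Protein.Group",
                    "PG.Q.Value", "Quantity", "Apex.Cycle", "IM",
                    "Mass.Error.PPM")

#' Read / write an analysis report
#'
#' Tab-separated report with one row per scored precursor candidate and the
#' columns `Precursor.Id`, `Run`, `Score`, `Q.Value`, `Protein.Group`,
#' `PG.Q.Value`, `Quantity`, `Apex.Cycle`, `IM`, `Mass.Error.PPM`.
#'
#' @param report Report `data.frame`.
#' @param path File path.
#' @return `read_report()` returns the report `data.frame`.
#' @export
write_report <- function(report, path) {
  stopifnot(all(REPORT_COLUMNS %in% names(report)))
  data.table::fwrite(report[, REPORT_COLUMNS], path, sep = "\t")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  missing_cols <- setdiff(REPORT_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("report format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  if (any(dt$Q.Value < 0 | dt$Q.Value > 1, na.rm = TRUE))
    stop("report format error: Q.Value outside [0, 1]")
  as.data.frame(dt)
}
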