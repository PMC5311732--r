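#' Write a metrics table as deterministic TSV
#'
#' Rows are sorted by `element_id` when present (otherwise by the first
#' column), columns keep their order, and numeric floating-point columns
#' are written with fixed precision (6 decimals), so two runs on the same
#' input produce byte-identical files.
#'
#' @param records data.frame.
#' @param path output path.
#' @param digits decimals for floating-point columns.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(records, path, digits = 6L) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    key <- if ("element_id" %in% names(records)) records$element_id
           else records[[1]]
    records <- records[order(key), , drop = FALSE]
  }
  for (cn in names(records)) {
    if (is.double(records[[cn]])) {
      records[[cn]] <- formatC(records[[cn]], format = "f",
                               digits = digits)
    }
  }
  ok <- tryCatch({
    write.table(records, file = path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write metrics table to ", path)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_metrics_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
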