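#' Write an evaluation table
#'
#' Writes the per-lead table from [evaluate_dataset()] with a final
#' `mean` row carrying the unweighted mean CR, as CSV (default) or JSON
#' (when `path` ends in `.json` and jsonlite is available).
#'
#' @param table data.frame of per-lead rows (needs at least a `cr`
#'   column), e.g. `evaluate_dataset(...)$table`.
#' @param path output path (`.csv` or `.json`).
#' @return invisibly, `path`.
#' @export
write_report <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) < 1L)
    stop("need a non-empty report table")
  if (!"cr" %in% names(table)) stop("report table must have a 'cr' column")
  mean_row <- table[1, , drop = FALSE]
  mean_row[] <- NA
  if ("record" %in% names(mean_row)) mean_row$record <- "mean"
  mean_row$cr <- mean(table$cr)
  out <- rbind(table, mean_row)
  if (tolower(tools::file_ext(path)) == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is needed for JSON reports")
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  } else {
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}
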