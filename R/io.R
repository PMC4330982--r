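counts_schema <- function() {
  c("individual_id", "group", "condition", "cell_index", "foci_count")
}

check_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data frame",
                                    call. = FALSE)
  missing_cols <- setdiff(counts_schema(), names(records))
  if (length(missing_cols) > 0) {
    stop("count table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) > 0) {
    if (any(!is.finite(records$foci_count)) || any(records$foci_count < 0)) {
      stop("foci_count must be a non-negative number", call. = FALSE)
    }
    check_condition(records$condition)
  }
  invisible(records)
}

#' Read and write per-cell foci count tables
#'
#' The shared CSV schema is
#' `individual_id,group,condition,cell_index,foci_count` -- one row per
#' scored cell. Reading validates the schema and reports every missing
#' column by name.
#'
#' @param records Count table data frame.
#' @param path CSV file path.
#' @return `read_counts()` returns the validated data frame.
#' @export
write_counts <- function(records, path) {
  check_records(records)
  write.csv(records[, counts_schema()], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  records <- read.csv(path, stringsAsFactors = FALSE)
  check_records(records)
  records
}

#' Write a cohort ground-truth table
#'
#' @param truth Truth table from [generate_cohort()].
#' @param path Output path; conventionally ends in `.truth.csv`.
#' @export
write_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
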