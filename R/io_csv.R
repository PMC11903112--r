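# CSV interchange: measurement tables and cohort manifests.
# Comma-separated, dot decimal, UTF-8, fixed headers.

.MEASUREMENT_COLS <- c(
  "nucleus_id", "case_id", "cell_class",
  "area_um2", "perimeter_um", "min_feret_um", "max_feret_um"
)

#' Write a measurement table to CSV
#'
#' Fixed header `nucleus_id,case_id,cell_class,area_um2,perimeter_um,
#' min_feret_um,max_feret_um`; values at full precision so that
#' write-then-read is lossless.
#'
#' @param records measurement tibble as produced by [measure_nuclei()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(records, path) {
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(records)[, .MEASUREMENT_COLS]
  for (col in .MEASUREMENT_COLS[4:7]) {
    df[[col]] <- sprintf("%.17g", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' @param path CSV file written by [write_measurements_csv()] (or any file
#'   with the same fixed header).
#' @return Measurement tibble; a hard error names the first missing
#'   required column.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character")
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(df))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(df[, .MEASUREMENT_COLS])
  for (col in .MEASUREMENT_COLS[4:7]) out[[col]] <- as.numeric(out[[col]])
  out
}

#' Read a cohort manifest from CSV
#'
#' Expects columns `case_id`, `variant_label` and optionally `group_role`.
#'
#' @param path CSV file path.
#' @return A [cohort_manifest()].
#' @export
read_manifest_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character")
  for (col in c("case_id", "variant_label")) {
    if (!col %in% names(df)) stop("missing required column(s): ", col)
  }
  cohort_manifest(df$case_id, df$variant_label,
                  if ("group_role" %in% names(df)) df$group_role else NULL)
}

#' Write a cohort manifest to CSV
#'
#' @param manifest a [cohort_manifest()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_manifest_csv <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
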