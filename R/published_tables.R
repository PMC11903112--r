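# Published pooled and per-case nuclear-size tables for the lobular
# carcinoma variants. These printed medians and quartiles are the
# calibration inputs for the synthetic generator and the reference values
# for the cut-off rule set.

#' Published pooled nuclear-size table for lobular carcinoma variants
#'
#' Median, 25th and 75th percentile, and printed IQR of the four nuclear
#' size parameters, pooled per variant (micrometres; area in square
#' micrometres). A handful of printed IQR values disagree slightly with
#' their own quartiles (Q3 - Q1), most plausibly a quantile-convention or
#' rounding artefact of the original statistics software; both the printed
#' value and the quartiles are retained so the discrepancy can be checked
#' with [check_printed_iqr()] rather than hidden.
#'
#' @return Tibble with columns `variant_label`, `parameter`, `median`,
#'   `q1`, `q3`, `iqr_printed`.
#' @export
variant_quartile_table <- function() {
  rows <- rbind(
    c("cLCIS",       "area",      32.7, 25.9, 40.0, 14.1),
    c("cLCIS",       "perimeter", 21.0, 18.8, 23.3, 4.5),
    c("cLCIS",       "min_feret",  5.7,  4.9,  6.3, 1.4),
    c("cLCIS",       "max_feret",  7.5,  6.7,  8.5, 1.8),
    c("pLCIS",       "area",      53.0, 41.1, 67.9, 26.2),
    c("pLCIS",       "perimeter", 27.1, 24.0, 30.4, 6.4),
    c("pLCIS",       "min_feret",  7.0,  6.1,  8.1, 2.0),
    c("pLCIS",       "max_feret",  9.9,  8.8, 11.2, 2.4),
    c("cILC_score1", "area",      34.1, 28.0, 41.7, 13.7),
    c("cILC_score1", "perimeter", 21.2, 19.3, 23.6, 4.3),
    c("cILC_score1", "min_feret",  5.8,  5.2,  6.4, 1.2),
    c("cILC_score1", "max_feret",  7.6,  6.8,  8.5, 1.7),
    c("cILC_score2", "area",      43.0, 34.7, 52.2, 17.5),
    c("cILC_score2", "perimeter", 24.0, 21.5, 26.6, 5.1),
    c("cILC_score2", "min_feret",  6.4,  5.8,  7.2, 1.4),
    c("cILC_score2", "max_feret",  8.6,  7.6,  9.7, 2.1),
    c("sILC_score2", "area",      40.4, 33.8, 48.0, 14.3),
    c("sILC_score2", "perimeter", 23.1, 21.1, 25.1, 4.0),
    c("sILC_score2", "min_feret",  6.5,  5.9,  7.1, 1.2),
    c("sILC_score2", "max_feret",  8.1,  7.3,  8.9, 1.6),
    c("pILC",        "area",      66.6, 50.1, 86.4, 36.3),
    c("pILC",        "perimeter", 30.0, 26.2, 34.2, 8.0),
    c("pILC",        "min_feret",  7.9,  6.7,  9.2, 2.5),
    c("pILC",        "max_feret", 10.9,  9.4, 12.5, 3.1)
  )
  tibble::tibble(
    variant_label = rows[, 1L],
    parameter = rows[, 2L],
    median = as.numeric(rows[, 3L]),
    q1 = as.numeric(rows[, 4L]),
    q3 = as.numeric(rows[, 5L]),
    iqr_printed = as.numeric(rows[, 6L])
  )
}

#' Published per-case nuclear-area table for pleomorphic ILC
#'
#' Median nuclear area with 25th/75th percentiles and printed IQR for the
#' 14 pleomorphic ILC cases, with their special cytomorphology (apocrine or
#' none) and printed size ratios to the three reference groups.
#'
#' @return Tibble with columns `case_id`, `median`, `q1`, `q3`,
#'   `iqr_printed`, `cytomorphology`, `ratio_lymphocyte`,
#'   `ratio_normal_epithelium`, `ratio_nst`.
#' @export
pilc_case_table <- function() {
  rows <- rbind(
    c("case_01", 75.7, 57.4,  98.2, 40.7, "none",     4.4, 3.2, 1.5),
    c("case_02", 47.0, 29.0,  66.1, 37.1, "none",     2.7, 2.0, 0.9),
    c("case_03", 56.2, 46.6,  67.5, 20.9, "none",     3.2, 2.4, 1.1),
    c("case_04", 76.7, 58.9,  94.7, 35.8, "none",     4.4, 3.3, 1.5),
    c("case_05", 82.5, 60.5, 107.9, 45.4, "none",     4.7, 3.5, 1.6),
    c("case_06", 80.7, 65.0,  92.8, 27.8, "none",     4.6, 3.6, 1.5),
    c("case_07", 76.2, 58.4,  96.4, 38.0, "none",     4.4, 3.3, 1.5),
    c("case_08", 61.9, 46.7,  75.9, 28.9, "apocrine", 3.6, 2.6, 1.2),
    c("case_09", 58.7, 48.3,  70.3, 22.0, "none",     3.4, 2.5, 1.2),
    c("case_10", 62.4, 52.1,  75.7, 23.7, "apocrine", 3.6, 2.7, 1.2),
    c("case_11", 62.0, 52.9,  63.9, 21.0, "apocrine", 3.6, 2.6, 1.2),
    c("case_12", 51.5, 36.7,  72.3, 35.6, "none",     3.0, 2.2, 1.0),
    c("case_13", 50.4, 40.0,  61.6, 21.6, "none",     3.0, 2.1, 1.0),
    c("case_14", 52.5, 30.3,  63.1, 32.8, "none",     3.0, 2.2, 1.0)
  )
  tibble::tibble(
    case_id = rows[, 1L],
    median = as.numeric(rows[, 2L]),
    q1 = as.numeric(rows[, 3L]),
    q3 = as.numeric(rows[, 4L]),
    iqr_printed = as.numeric(rows[, 5L]),
    cytomorphology = rows[, 6L],
    ratio_lymphocyte = as.numeric(rows[, 7L]),
    ratio_normal_epithelium = as.numeric(rows[, 8L]),
    ratio_nst = as.numeric(rows[, 9L])
  )
}

#' Recompute IQRs from printed quartiles and flag consistency
#'
#' For every row of a quartile table, recomputes IQR = Q3 - Q1 and compares
#' it with the printed IQR at one-decimal rounding. Rows where the printed
#' value disagrees with its own quartiles are flagged, not corrected.
#'
#' @param table a tibble with columns `q1`, `q3`, `iqr_printed` (e.g.
#'   [variant_quartile_table()] or [pilc_case_table()]).
#' @return The input with extra columns `iqr_recomputed` (rounded to one
#'   decimal) and `consistent` (logical).
#' @export
check_printed_iqr <- function(table) {
  stopifnot(all(c("q1", "q3", "iqr_printed") %in% names(table)))
  out <- table
  out$iqr_recomputed <- round(out$q3 - out$q1, 1)
  out$consistent <- abs(out$iqr_recomputed - out$iqr_printed) < 0.05
  out
}
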