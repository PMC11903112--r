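# Median/quartile/IQR summaries per case and per pooled variant, and
# lesion-to-reference size ratios.

.PARAMS <- c("area_um2", "perimeter_um", "min_feret_um", "max_feret_um")

#' Quantile with a selectable interpolation convention
#'
#' Two conventions are exposed because the common linear-interpolation rule
#' (position h = (n - 1) p + 1 on the sorted sample) and SPSS's default
#' weighted-average rule (h = (n + 1) p) disagree on small samples, and
#' clinical studies frequently report SPSS output. `p = 0.5` reduces to the
#' median under both.
#'
#' @param values non-empty numeric vector, all finite.
#' @param p quantile fraction in \eqn{[0, 1]}.
#' @param method `"interp_linear"` (default) or `"spss_haverage"`.
#' @return The interpolated quantile.
#' @examples
#' lob_quantile(c(10, 20, 30, 40), 0.25)                    # 17.5
#' lob_quantile(c(10, 20, 30, 40), 0.25, "spss_haverage")   # 12.5
#' @export
lob_quantile <- function(values, p, method = c("interp_linear", "spss_haverage")) {
  method <- match.arg(method)
  if (!length(values)) stop("cannot take a quantile of an empty vector")
  if (!all(is.finite(values))) stop("values must all be finite")
  type <- switch(method, interp_linear = 7L, spss_haverage = 6L)
  unname(stats::quantile(values, probs = p, type = type))
}

#' Summarise nucleus measurements per case or per pooled variant
#'
#' For each of the four size parameters, computes the median, the 25th and
#' 75th percentiles, and the interquartile range (always recomputed as
#' Q3 - Q1, never trusted from input files). With
#' `pooling = "pooled_by_variant"` all nuclei of a variant's cases are
#' pooled into one summary per variant.
#'
#' @param records measurement tibble ([measure_nuclei()] columns).
#' @param manifest a [cohort_manifest()] covering every `case_id` present
#'   in `records`.
#' @param pooling `"per_case"` or `"pooled_by_variant"`.
#' @param quantile_method passed to [lob_quantile()].
#' @param cell_class restrict to one cell class before summarising
#'   (default `"tumour"`); `NULL` keeps all classes.
#' @return Tibble with one row per case (or variant), columns `case_id`,
#'   `variant_label`, `n_nuclei`, and `median_`/`q1_`/`q3_`/`iqr_` for each
#'   of `area`, `perimeter`, `min_feret`, `max_feret`. Cases with no nuclei
#'   are omitted with a warning.
#' @export
summarize_cases <- function(records, manifest,
                            pooling = c("per_case", "pooled_by_variant"),
                            quantile_method = "interp_linear",
                            cell_class = "tumour") {
  pooling <- match.arg(pooling)
  stopifnot(inherits(manifest, "cohort_manifest"))
  unknown <- setdiff(unique(records$case_id), manifest$case_id)
  if (length(unknown)) {
    stop("case_id not in manifest: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cell_class)) {
    records <- records[records$cell_class %in% cell_class, , drop = FALSE]
  }
  records$variant_label <-
    manifest$variant_label[match(records$case_id, manifest$case_id)]

  if (pooling == "per_case") {
    groups <- manifest$case_id
    key_col <- "case_id"
  } else {
    groups <- unique(manifest$variant_label)
    key_col <- "variant_label"
  }
  rows <- lapply(groups, function(g) {
    sub <- records[records[[key_col]] == g, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no nuclei for ", key_col, " '", g, "'; omitted")
      return(NULL)
    }
    out <- tibble::tibble(
      case_id = if (key_col == "case_id") g else NA_character_,
      variant_label = sub$variant_label[1L],
      n_nuclei = nrow(sub)
    )
    if (key_col == "variant_label") out$variant_label <- g
    for (p in .PARAMS) {
      nm <- sub("_um2?$", "", p)
      x <- sub[[p]]
      q1 <- lob_quantile(x, 0.25, quantile_method)
      q3 <- lob_quantile(x, 0.75, quantile_method)
      out[[paste0("median_", nm)]] <- lob_quantile(x, 0.5, quantile_method)
      out[[paste0("q1_", nm)]] <- q1
      out[[paste0("q3_", nm)]] <- q3
      out[[paste0("iqr_", nm)]] <- q3 - q1
    }
    out
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Lesion-to-reference size ratios
#'
#' Ratios of lesion medians to reference medians, per parameter, reported
#' both raw and rounded to one decimal (the display convention of clinical
#' morphometry tables).
#'
#' @param lesion,reference single summary rows from [summarize_cases()].
#' @return Tibble with columns `parameter`, `lesion_median`,
#'   `reference_median`, `ratio`, `ratio_displayed`.
#' @export
reference_ratio <- function(lesion, reference) {
  stopifnot(nrow(lesion) == 1L, nrow(reference) == 1L)
  params <- c("area", "perimeter", "min_feret", "max_feret")
  rows <- lapply(params, function(nm) {
    lm <- lesion[[paste0("median_", nm)]]
    rm_ <- reference[[paste0("median_", nm)]]
    if (!is.finite(rm_) || rm_ == 0) stop("reference median is zero for ", nm)
    tibble::tibble(
      parameter = nm,
      lesion_median = lm,
      reference_median = rm_,
      ratio = lm / rm_,
      ratio_displayed = round(lm / rm_, 1)
    )
  })
  do.call(rbind, rows)
}

#' Two-group comparison of one nuclear parameter
#'
#' Thin convenience wrapper: two-sided Mann-Whitney U (default) or Welch t
#' comparison of one measurement column between two groups of nuclei.
#'
#' @param x,y numeric vectors for the two groups.
#' @param test `"mann_whitney"` or `"t"`.
#' @return Tibble with columns `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(x, y, test = c("mann_whitney", "t")) {
  test <- match.arg(test)
  res <- if (test == "mann_whitney") {
    stats::wilcox.test(x, y, exact = FALSE)
  } else {
    stats::t.test(x, y)
  }
  tibble::tibble(
    test = test,
    statistic = unname(res$statistic),
    p_value = res$p.value
  )
}
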