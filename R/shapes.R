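# NucleusShape: one nucleus boundary polygon in calibrated micrometre
# coordinates, carrying its case and cell-class labels.

.CELL_CLASSES <- c("tumour", "lymphocyte", "normal_epithelium", "other")

.VARIANT_LABELS <- c(
  "cLCIS", "pLCIS",
  "cILC_score1", "cILC_score2", "sILC_score2", "pILC",
  "IBC_NST_score1", "IBC_NST_score2", "IBC_NST_score3",
  "lymphocyte", "normal_epithelium"
)

.GROUP_ROLES <- c("lesion", "reference")

#' Construct a nucleus boundary shape
#'
#' A `nucleus_shape` is a closed simple polygon in micrometre coordinates
#' together with a nucleus identifier, a case identifier and a cell class.
#' The ring is stored open (the first vertex is not repeated at the end) and
#' normalised to counter-clockwise orientation in a y-up mathematical frame.
#' Self-intersecting ("bow-tie") rings, which segmentation exports
#' occasionally contain, are repaired by keeping the largest simple sub-ring
#' when that is possible, and rejected otherwise.
#'
#' @param vertices two-column numeric matrix of (x, y) vertices in
#'   micrometres; a closing duplicate of the first vertex is dropped.
#' @param nucleus_id,case_id opaque identifier strings.
#' @param cell_class one of `"tumour"`, `"lymphocyte"`,
#'   `"normal_epithelium"`, `"other"`.
#' @param source_pixel_size optional scalar, the micrometres-per-pixel
#'   calibration of the image the boundary came from.
#' @return An object of class `nucleus_shape`: a list with fields
#'   `nucleus_id`, `case_id`, `cell_class`, `vertices`, `source_pixel_size`.
#' @examples
#' sq <- nucleus_shape(cbind(c(0, 2.5, 2.5, 0), c(0, 0, 2.5, 2.5)), "n1", "case1")
#' polygon_area(sq$vertices)  # 6.25
#' @export
nucleus_shape <- function(vertices, nucleus_id = "n1", case_id = "case1",
                          cell_class = "tumour", source_pixel_size = NULL) {
  cell_class <- match.arg(cell_class, .CELL_CLASSES)
  v <- clean_ring(vertices)
  structure(
    list(
      nucleus_id = as.character(nucleus_id),
      case_id = as.character(case_id),
      cell_class = cell_class,
      vertices = v,
      source_pixel_size = source_pixel_size
    ),
    class = "nucleus_shape"
  )
}

#' @export
print.nucleus_shape <- function(x, ...) {
  cat(sprintf(
    "<nucleus_shape %s | case %s | %s | %d vertices | area %.2f um^2>\n",
    x$nucleus_id, x$case_id, x$cell_class, nrow(x$vertices),
    polygon_area(x$vertices)
  ))
  invisible(x)
}

# Normalise a raw vertex list into a valid open CCW simple ring.
clean_ring <- function(vertices) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L) stop("vertices must be a two-column (x, y) matrix")
  if (!all(is.finite(v))) stop("vertices must all be finite")
  n <- nrow(v)
  if (n >= 2L && isTRUE(all.equal(v[1L, ], v[n, ], tolerance = 1e-12,
                                  check.attributes = FALSE))) {
    v <- v[-n, , drop = FALSE]
  }
  # drop consecutive duplicates
  if (nrow(v) >= 2L) {
    keep <- c(TRUE, rowSums(abs(diff(v))) > 0)
    v <- v[keep, , drop = FALSE]
  }
  if (nrow(v) < 3L) stop("a polygon ring needs at least 3 distinct vertices")
  if (!ring_is_simple(v)) {
    # a bow-tie has cancelling lobes, so test simplicity before area
    v <- repair_ring(v)
    if (is.null(v)) stop("self-intersecting ring could not be repaired")
  }
  if (abs(signed_area(v)) <= 0) stop("zero-area polygon")
  if (signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  dimnames(v) <- NULL
  v
}

signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Proper-crossing test for two closed segments, excluding shared endpoints.
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

# O(n^2) simplicity check on the edge set, vectorized over all
# non-adjacent edge pairs; adequate for nucleus boundaries (tens to low
# hundreds of vertices).
ring_is_simple <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  idx <- which(upper.tri(matrix(NA, n, n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  keep <- (j != i + 1L) & !(i == 1L & j == n)
  i <- i[keep]; j <- j[keep]
  if (!length(i)) return(TRUE)
  a1 <- v[i, , drop = FALSE]; a2 <- v[nxt[i], , drop = FALSE]
  b1 <- v[j, , drop = FALSE]; b2 <- v[nxt[j], , drop = FALSE]
  cr <- function(a, b, c) {
    (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
      (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
  }
  d1 <- cr(b1, b2, a1); d2 <- cr(b1, b2, a2)
  d3 <- cr(a1, a2, b1); d4 <- cr(a1, a2, b2)
  !any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
         ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

# Bow-tie repair: split the ring at the first proper edge crossing into two
# sub-rings and keep the larger simple one; recurse a bounded number of times.
repair_ring <- function(v, depth = 4L) {
  if (depth <= 0L) return(NULL)
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (!.segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) next
      p <- .segment_intersection(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])
      ring_a <- rbind(p, v[(i + 1L):j, , drop = FALSE])
      idx_b <- if (nxt[j] <= i) nxt[j]:i else c(nxt[j]:n, seq_len(i))
      ring_b <- rbind(p, v[idx_b, , drop = FALSE])
      cand <- list(ring_a, ring_b)
      cand <- Filter(function(r) nrow(unique(r)) >= 3L, cand)
      if (!length(cand)) return(NULL)
      areas <- vapply(cand, function(r) abs(signed_area(r)), numeric(1))
      best <- cand[[which.max(areas)]]
      if (!ring_is_simple(best)) best <- repair_ring(best, depth - 1L)
      return(best)
    }
  }
  v
}

.segment_intersection <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  den <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / den
  p1 + t * d1
}

#' Construct a cohort manifest
#'
#' Maps each case identifier to its variant label and its role in the
#' analysis (lesion under study versus internal size reference).
#'
#' @param case_id character vector of unique case identifiers.
#' @param variant_label one of the closed study vocabulary: cLCIS, pLCIS,
#'   cILC_score1, cILC_score2, sILC_score2, pILC, IBC_NST_score1,
#'   IBC_NST_score2, IBC_NST_score3, lymphocyte, normal_epithelium.
#' @param group_role `"lesion"` or `"reference"`; defaults to `"reference"`
#'   for lymphocyte and normal-epithelium entries and `"lesion"` otherwise.
#' @return A tibble of class `cohort_manifest` with columns `case_id`,
#'   `variant_label`, `group_role`.
#' @export
cohort_manifest <- function(case_id, variant_label, group_role = NULL) {
  case_id <- as.character(case_id)
  variant_label <- as.character(variant_label)
  if (anyDuplicated(case_id)) stop("case_id values must be unique")
  bad <- setdiff(unique(variant_label), .VARIANT_LABELS)
  if (length(bad)) {
    stop("unknown variant_label: ", paste(bad, collapse = ", "))
  }
  if (is.null(group_role)) {
    group_role <- ifelse(
      variant_label %in% c("lymphocyte", "normal_epithelium"),
      "reference", "lesion"
    )
  }
  if (!all(group_role %in% .GROUP_ROLES)) {
    stop("group_role must be 'lesion' or 'reference'")
  }
  out <- tibble::tibble(
    case_id = case_id,
    variant_label = variant_label,
    group_role = group_role
  )
  class(out) <- c("cohort_manifest", class(out))
  out
}

#' Variant labels recognised by the cohort manifest
#' @return Character vector of the closed variant vocabulary.
#' @export
variant_labels <- function() .VARIANT_LABELS
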