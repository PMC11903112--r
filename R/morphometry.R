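# The four nuclear size parameters: area, perimeter, minimum and maximum
# Feret diameter, computed from a boundary polygon in micrometres.

#' Polygon area (shoelace)
#'
#' Absolute area enclosed by a simple ring, independent of orientation and
#' of the image-frame handedness.
#'
#' @param vertices two-column (x, y) matrix; open ring (first vertex not
#'   repeated).
#' @return Area in the square of the coordinate unit.
#' @export
polygon_area <- function(vertices) {
  v <- .as_ring(vertices)
  a <- abs(signed_area(v))
  if (a == 0) stop("zero-area polygon")
  a
}

#' Polygon perimeter
#'
#' Sum of Euclidean edge lengths including the closing edge.
#'
#' @inheritParams polygon_area
#' @return Perimeter in the coordinate unit.
#' @export
polygon_perimeter <- function(vertices) {
  v <- .as_ring(vertices)
  d <- diff(rbind(v, v[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Convex hull of a point set
#'
#' Minimal convex polygon containing the points, returned counter-clockwise
#' with collinear points on hull edges removed.
#'
#' @param vertices two-column (x, y) matrix, at least 3 points.
#' @return Two-column matrix of hull vertices in counter-clockwise order.
#' @export
convex_hull <- function(vertices) {
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (nrow(v) < 3L) stop("need at least 3 points")
  idx <- rev(grDevices::chull(v))  # chull is clockwise; reverse to CCW
  h <- v[idx, , drop = FALSE]
  h <- .drop_collinear(h)
  if (nrow(h) < 3L) stop("all points are collinear")
  dimnames(h) <- NULL
  h
}

.drop_collinear <- function(h, tol = 0) {
  repeat {
    n <- nrow(h)
    if (n < 3L) return(h)
    prv <- c(n, seq_len(n - 1L))
    nxt <- c(seq_len(n)[-1L], 1L)
    cross <- (h[, 1L] - h[prv, 1L]) * (h[nxt, 2L] - h[, 2L]) -
      (h[, 2L] - h[prv, 2L]) * (h[nxt, 1L] - h[, 1L])
    keep <- abs(cross) > tol
    if (all(keep)) return(h)
    h <- h[keep, , drop = FALSE]
  }
}

#' Maximum Feret diameter
#'
#' The longest caliper distance of the shape: the maximum pairwise distance
#' between vertices, attained on the convex hull.
#'
#' @inheritParams polygon_area
#' @return Maximum Feret diameter in the coordinate unit.
#' @export
max_feret <- function(vertices) {
  h <- convex_hull(.as_ring(vertices))
  d2 <- as.matrix(stats::dist(h))^2
  sqrt(max(d2))
}

#' Minimum Feret diameter
#'
#' The smallest caliper width of the shape: the minimum over convex-hull
#' edges of the farthest hull-vertex distance to that edge's supporting
#' line. The minimum width of a convex polygon is always perpendicular to
#' one of its edges, so this edge scan is exact.
#'
#' @inheritParams polygon_area
#' @return Minimum Feret diameter in the coordinate unit.
#' @export
min_feret <- function(vertices) {
  h <- convex_hull(.as_ring(vertices))
  n <- nrow(h)
  nxt <- c(seq_len(n)[-1L], 1L)
  widths <- vapply(seq_len(n), function(i) {
    e <- h[nxt[i], ] - h[i, ]
    len <- sqrt(sum(e^2))
    # distance of every hull vertex to the supporting line of edge i
    d <- abs((h[, 1L] - h[i, 1L]) * e[2L] - (h[, 2L] - h[i, 2L]) * e[1L]) / len
    max(d)
  }, numeric(1))
  min(widths)
}

#' Measure one nucleus
#'
#' Assembles the four nuclear size parameters for a [nucleus_shape()].
#'
#' @param shape a `nucleus_shape`.
#' @return One-row tibble with columns `nucleus_id`, `case_id`,
#'   `cell_class`, `area_um2`, `perimeter_um`, `min_feret_um`,
#'   `max_feret_um`.
#' @export
measure_nucleus <- function(shape) {
  stopifnot(inherits(shape, "nucleus_shape"))
  v <- shape$vertices
  tibble::tibble(
    nucleus_id = shape$nucleus_id,
    case_id = shape$case_id,
    cell_class = shape$cell_class,
    area_um2 = polygon_area(v),
    perimeter_um = polygon_perimeter(v),
    min_feret_um = min_feret(v),
    max_feret_um = max_feret(v)
  )
}

#' Measure a list of nuclei
#'
#' @param shapes list of `nucleus_shape` objects.
#' @return Tibble with one row per nucleus, columns as in
#'   [measure_nucleus()].
#' @export
measure_nuclei <- function(shapes) {
  if (!length(shapes)) return(.empty_measurements())
  tibble::tibble(
    nucleus_id = vapply(shapes, function(s) s$nucleus_id, character(1)),
    case_id = vapply(shapes, function(s) s$case_id, character(1)),
    cell_class = vapply(shapes, function(s) s$cell_class, character(1)),
    area_um2 = vapply(shapes, function(s) polygon_area(s$vertices), numeric(1)),
    perimeter_um = vapply(shapes, function(s) polygon_perimeter(s$vertices), numeric(1)),
    min_feret_um = vapply(shapes, function(s) min_feret(s$vertices), numeric(1)),
    max_feret_um = vapply(shapes, function(s) max_feret(s$vertices), numeric(1))
  )
}

.empty_measurements <- function() {
  tibble::tibble(
    nucleus_id = character(), case_id = character(), cell_class = character(),
    area_um2 = numeric(), perimeter_um = numeric(),
    min_feret_um = numeric(), max_feret_um = numeric()
  )
}

.as_ring <- function(vertices) {
  if (inherits(vertices, "nucleus_shape")) return(vertices$vertices)
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  if (ncol(v) != 2L || nrow(v) < 3L) {
    stop("vertices must be a two-column matrix with at least 3 rows")
  }
  if (!all(is.finite(v))) stop("vertices must all be finite")
  n <- nrow(v)
  if (isTRUE(all.equal(v[1L, ], v[n, ], tolerance = 1e-12,
                       check.attributes = FALSE))) {
    v <- v[-n, , drop = FALSE]
  }
  v
}
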