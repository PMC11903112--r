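# Independent brute-force oracles used to check the geometry and
# statistics code, plus small fixture generators. These deliberately avoid
# the implementation paths they verify.

# Random star-shaped simple polygon: sorted angles, random radii.
rand_star_polygon <- function(n = 12L, r_range = c(0.5, 2)) {
  theta <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_range[1L], r_range[2L])
  cbind(r * cos(theta), r * sin(theta))
}

# Maximum Feret: exhaustive scan over all vertex pairs of the raw ring.
oracle_max_feret <- function(v) {
  max(stats::dist(v))
}

# Minimum Feret: dense angle sweep of the projected width.
oracle_min_feret <- function(v, n_angles = 3600L) {
  ang <- pi * (seq_len(n_angles) - 1L) / n_angles
  widths <- vapply(ang, function(a) {
    p <- v[, 1L] * cos(a) + v[, 2L] * sin(a)
    max(p) - min(p)
  }, numeric(1))
  min(widths)
}

# Convex hull by the O(n^3) half-plane test: a directed segment (i, j) is
# a hull edge iff every other point lies strictly on its left; hull
# vertices are the endpoints of hull edges.
oracle_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    cr <- (b[1] - a[1]) * (pts[, 2L] - a[2]) -
      (b[2] - a[2]) * (pts[, 1L] - a[1])
    if (all(cr[-c(i, j)] > 1e-12)) {
      on_hull[i] <- TRUE
      on_hull[j] <- TRUE
    }
  }
  pts[on_hull, , drop = FALSE]
}

# AUC as the explicit pairwise concordance count, ties counted one half.
oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Monte-Carlo area estimate by rejection sampling with an independent
# crossing-number point-in-polygon test.
oracle_area_mc <- function(v, n = 1e6) {
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  px <- stats::runif(n, lo[1L], hi[1L])
  py <- stats::runif(n, lo[2L], hi[2L])
  m <- nrow(v)
  inside <- rep(FALSE, n)
  j <- m
  for (i in seq_len(m)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]; xj <- v[j, 1L]; yj <- v[j, 2L]
    cr <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cr)
    j <- i
  }
  frac <- mean(inside)
  box <- prod(hi - lo)
  list(
    estimate = frac * box,
    se = box * sqrt(frac * (1 - frac) / n)
  )
}

# Rotate a ring by `ang` radians about the origin.
rotate_ring <- function(v, ang) {
  cbind(cos(ang) * v[, 1L] - sin(ang) * v[, 2L],
        sin(ang) * v[, 1L] + cos(ang) * v[, 2L])
}

# A small irregular 9-gon fixture (star-shaped, fixed vertices).
ninegon_fixture <- function() {
  theta <- 2 * pi * (0:8) / 9
  r <- c(1.8, 1.1, 2.2, 0.9, 1.5, 2.0, 1.2, 1.7, 1.0)
  cbind(r * cos(theta), r * sin(theta))
}

# Regular n-gon of circumradius r.
regular_ngon <- function(n, r = 1) {
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(r * cos(theta), r * sin(theta))
}
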