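# Synthetic nucleus populations: a lognormal nuclear-area law calibrated to
# published quartiles, ellipse-based boundary polygons with smooth radial
# noise, per-case heterogeneity, and rasterization to label masks. This is
# the data source the rest of the pipeline is tested against.

#' Generative parameters for one variant's nucleus population
#'
#' Areas follow a lognormal law (log-median `mu`, log-scale `sigma`);
#' nuclei are rendered as randomly rotated ellipse-based polygons with
#' low-order radial boundary noise; cases within a variant get a
#' multiplicative median shift (additive on logs) with standard deviation
#' `case_heterogeneity`.
#'
#' @param variant_label variant this spec generates (see [variant_labels()]).
#' @param mu log-median of nuclear area; `exp(mu)` is the target median in
#'   square micrometres.
#' @param sigma log-scale of nuclear area, >= 0.
#' @param eccentricity_range length-2 interval in \eqn{[0, 1)} from which
#'   per-nucleus ellipse eccentricity is drawn uniformly.
#' @param boundary_noise relative radial noise amplitude, < 0.5 so rings
#'   stay simple and star-convex.
#' @param n_vertices vertices per rendered polygon, >= 3.
#' @param case_heterogeneity log-scale SD of the per-case median shift.
#' @param nuclei_per_case integer count, or length-2 range sampled
#'   uniformly per case.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(variant_label, mu, sigma,
                           eccentricity_range = c(0.3, 0.7),
                           boundary_noise = 0.05,
                           n_vertices = 96L,
                           case_heterogeneity = 0.17,
                           nuclei_per_case = c(100L, 600L)) {
  stopifnot(
    variant_label %in% .VARIANT_LABELS,
    is.finite(mu), sigma >= 0,
    length(eccentricity_range) == 2L,
    all(eccentricity_range >= 0), all(eccentricity_range < 1),
    eccentricity_range[1L] <= eccentricity_range[2L],
    boundary_noise >= 0, boundary_noise < 0.5,
    n_vertices >= 3L,
    case_heterogeneity >= 0,
    all(nuclei_per_case >= 3L)
  )
  structure(
    list(
      variant_label = variant_label, mu = mu, sigma = sigma,
      eccentricity_range = eccentricity_range,
      boundary_noise = boundary_noise,
      n_vertices = as.integer(n_vertices),
      case_heterogeneity = case_heterogeneity,
      nuclei_per_case = as.integer(nuclei_per_case)
    ),
    class = "synthetic_spec"
  )
}

#' Calibrate a lognormal area law from printed quartiles
#'
#' Under a lognormal law the median fixes the log-location
#' (`mu = ln median`) and the quartile ratio fixes the log-scale
#' (`sigma = ln(q3/q1) / (2 z_0.75)` with `z_0.75 = 0.67449`, the 75th
#' standard-normal percentile). A lognormal has symmetric quartiles on the
#' log scale, so `|ln(q3/median) - ln(median/q1)|` is reported as a
#' diagnostic of how far the printed quartiles depart from the assumed law.
#'
#' @param median,q1,q3 printed median and 25th/75th percentiles,
#'   `0 < q1 < median < q3`.
#' @return List with `mu`, `sigma`, `asymmetry` (the log-quartile symmetry
#'   diagnostic).
#' @examples
#' fit_lognormal_from_quartiles(66.6, 50.1, 86.4)  # mu ~ 4.199, sigma ~ 0.404
#' @export
fit_lognormal_from_quartiles <- function(median, q1, q3) {
  if (!(0 < q1 && q1 < median && median < q3)) {
    stop("need 0 < q1 < median < q3")
  }
  z75 <- stats::qnorm(0.75)
  list(
    mu = log(median),
    sigma = log(q3 / q1) / (2 * z75),
    asymmetry = abs(log(q3 / median) - log(median / q1))
  )
}

#' Synthetic specs calibrated to the published variant table
#'
#' One [synthetic_spec()] per lobular carcinoma variant, with the area law
#' calibrated to the published pooled median and quartiles
#' ([variant_quartile_table()]).
#'
#' @inheritParams synthetic_spec
#' @return Named list of `synthetic_spec` objects.
#' @export
variant_synthetic_specs <- function(eccentricity_range = c(0.3, 0.7),
                                    boundary_noise = 0.05,
                                    n_vertices = 96L,
                                    case_heterogeneity = 0.17,
                                    nuclei_per_case = c(100L, 600L)) {
  tab <- variant_quartile_table()
  tab <- tab[tab$parameter == "area", , drop = FALSE]
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    law <- fit_lognormal_from_quartiles(tab$median[i], tab$q1[i], tab$q3[i])
    synthetic_spec(
      tab$variant_label[i], law$mu, law$sigma,
      eccentricity_range = eccentricity_range,
      boundary_noise = boundary_noise,
      n_vertices = n_vertices,
      case_heterogeneity = case_heterogeneity,
      nuclei_per_case = nuclei_per_case
    )
  })
  stats::setNames(specs, tab$variant_label)
}

# Evaluate code with a temporary RNG state; the caller's stream is
# untouched.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    }
  })
  set.seed(seed)
  force(code)
}

#' Render one synthetic nucleus boundary polygon
#'
#' An ellipse with the requested eccentricity, perturbed by smooth radial
#' noise (Fourier modes 2-6, total relative amplitude `boundary_noise`),
#' randomly rotated, and rescaled so the polygon area equals `area` to
#' within 1e-9 relative. The noise amplitude bound keeps the ring simple
#' and star-convex.
#'
#' @param area target polygon area in square micrometres.
#' @param eccentricity ellipse eccentricity in \eqn{[0, 1)}.
#' @param boundary_noise relative radial noise amplitude in \eqn{[0, 0.5)}.
#' @param n_vertices number of polygon vertices.
#' @param seed optional integer; when given, rendering is a pure function
#'   of its arguments and the caller's RNG stream is untouched.
#' @param nucleus_id,case_id,cell_class labels for the resulting shape.
#' @return A [nucleus_shape()].
#' @export
render_nucleus_polygon <- function(area, eccentricity = 0, boundary_noise = 0,
                                   n_vertices = 96L, seed = NULL,
                                   nucleus_id = "n1", case_id = "case1",
                                   cell_class = "tumour") {
  stopifnot(area > 0, eccentricity >= 0, eccentricity < 1,
            boundary_noise >= 0, boundary_noise < 0.5, n_vertices >= 3L)
  render <- function() {
    theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
    b_over_a <- sqrt(1 - eccentricity^2)
    r <- rep(1, n_vertices)
    if (boundary_noise > 0) {
      modes <- 2:6
      amp <- stats::runif(length(modes))
      amp <- amp / sum(amp) * boundary_noise
      phase <- stats::runif(length(modes), 0, 2 * pi)
      for (k in seq_along(modes)) {
        r <- r + amp[k] * cos(modes[k] * theta + phase[k])
      }
    }
    x <- r * cos(theta)
    y <- r * b_over_a * sin(theta)
    rot <- stats::runif(1, 0, 2 * pi)
    v <- cbind(cos(rot) * x - sin(rot) * y, sin(rot) * x + cos(rot) * y)
    v * sqrt(area / abs(signed_area(v)))
  }
  v <- if (is.null(seed)) render() else with_seed(seed, render())
  nucleus_shape(v, nucleus_id = nucleus_id, case_id = case_id,
                cell_class = cell_class)
}

#' Simulate a whole cohort of nucleus boundaries
#'
#' For each variant spec and case, draws a per-case median shift from the
#' spec's heterogeneity law, samples nuclear areas from the shifted
#' lognormal, and renders each nucleus as a boundary polygon. Fully
#' reproducible from `seed`.
#'
#' @param specs list of [synthetic_spec()] objects (one per variant).
#' @param n_cases_per_variant cases to generate per spec.
#' @param seed integer seed.
#' @param nuclei_per_case optional override of each spec's per-case count
#'   (integer, or length-2 range).
#' @return List with `shapes` (list of [nucleus_shape()]), `manifest`
#'   (a [cohort_manifest()]) and `ground_truth` (tibble of per-case
#'   generating parameters: `case_id`, `variant_label`, `mu_case`, `sigma`,
#'   `target_median_area`, `n_nuclei`).
#' @export
simulate_cohort <- function(specs, n_cases_per_variant, seed,
                            nuclei_per_case = NULL) {
  if (inherits(specs, "synthetic_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, logical(1), "synthetic_spec")))
  with_seed(seed, {
    shapes <- vector("list", 0L)
    gt <- list()
    man_case <- character()
    man_variant <- character()
    for (sp in specs) {
      for (ci in seq_len(n_cases_per_variant)) {
        case_id <- sprintf("%s_case%02d", sp$variant_label, ci)
        shift <- if (sp$case_heterogeneity > 0) {
          stats::rnorm(1, 0, sp$case_heterogeneity)
        } else 0
        npc <- nuclei_per_case %||% sp$nuclei_per_case
        n_nuc <- if (length(npc) > 1L) {
          sample(npc[1L]:npc[2L], 1L)
        } else as.integer(npc)
        areas <- stats::rlnorm(n_nuc, sp$mu + shift, sp$sigma)
        ecc <- stats::runif(n_nuc, sp$eccentricity_range[1L],
                            sp$eccentricity_range[2L])
        for (k in seq_len(n_nuc)) {
          shapes[[length(shapes) + 1L]] <- render_nucleus_polygon(
            areas[k], ecc[k], sp$boundary_noise, sp$n_vertices,
            nucleus_id = sprintf("%s_n%04d", case_id, k),
            case_id = case_id
          )
        }
        man_case <- c(man_case, case_id)
        man_variant <- c(man_variant, sp$variant_label)
        gt[[length(gt) + 1L]] <- tibble::tibble(
          case_id = case_id,
          variant_label = sp$variant_label,
          mu_case = sp$mu + shift,
          sigma = sp$sigma,
          target_median_area = exp(sp$mu + shift),
          n_nuclei = n_nuc
        )
      }
    }
    list(
      shapes = shapes,
      manifest = cohort_manifest(man_case, man_variant),
      ground_truth = do.call(rbind, gt)
    )
  })
}

#' Rasterize nucleus shapes into integer label masks
#'
#' Places each shape's bounding box on square tiles by greedy shelf
#' packing (non-overlapping, with a margin) and paints pixels whose
#' centres fall inside the polygon with the shape's label.
#'
#' @param shapes list of [nucleus_shape()] objects.
#' @param pixel_size micrometres per pixel.
#' @param tile_size tile side length in pixels.
#' @param margin_px clearance between placed shapes and tile borders, in
#'   pixels.
#' @return List with `masks` (list of integer matrices) and `placement`
#'   (tibble: `nucleus_id`, `tile`, `label`, `offset_x_um`, `offset_y_um`).
#'   Labels are unique within a tile.
#' @export
rasterize_cohort <- function(shapes, pixel_size, tile_size = 512L,
                             margin_px = 3L) {
  masks <- list(matrix(0L, tile_size, tile_size))
  placement <- list()
  cur_tile <- 1L
  shelf_x <- margin_px
  shelf_y <- margin_px
  shelf_h <- 0L
  label <- 0L
  for (s in shapes) {
    vpx <- s$vertices / pixel_size
    lo <- apply(vpx, 2L, min)
    hi <- apply(vpx, 2L, max)
    w <- ceiling(hi[1L] - lo[1L]) + 2L
    h <- ceiling(hi[2L] - lo[2L]) + 2L
    if (w + 2L * margin_px > tile_size || h + 2L * margin_px > tile_size) {
      stop("shape '", s$nucleus_id, "' is larger than the tile")
    }
    if (shelf_x + w + margin_px > tile_size) {  # new shelf
      shelf_x <- margin_px
      shelf_y <- shelf_y + shelf_h + margin_px
      shelf_h <- 0L
    }
    if (shelf_y + h + margin_px > tile_size) {  # new tile
      masks[[length(masks) + 1L]] <- matrix(0L, tile_size, tile_size)
      cur_tile <- length(masks)
      shelf_x <- margin_px
      shelf_y <- margin_px
      shelf_h <- 0L
      label <- 0L
    }
    # shift polygon so its bbox lower corner sits at (shelf_x+1, shelf_y+1)
    off <- c(shelf_x + 1 - lo[1L], shelf_y + 1 - lo[2L])
    vloc <- sweep(vpx, 2L, -off)
    label <- label + 1L
    cols <- max(1L, floor(shelf_x)):min(tile_size, ceiling(shelf_x + w + 1))
    rows <- max(1L, floor(shelf_y)):min(tile_size, ceiling(shelf_y + h + 1))
    grid <- expand.grid(x = cols, y = rows)
    inside <- point_in_polygon(grid$x, grid$y, vloc)
    if (any(inside)) {
      m <- masks[[cur_tile]]
      m[cbind(grid$y[inside], grid$x[inside])] <- label
      masks[[cur_tile]] <- m
    }
    placement[[length(placement) + 1L]] <- tibble::tibble(
      nucleus_id = s$nucleus_id, tile = cur_tile, label = label,
      offset_x_um = off[1L] * pixel_size, offset_y_um = off[2L] * pixel_size
    )
    shelf_x <- shelf_x + w + margin_px
    shelf_h <- max(shelf_h, h)
  }
  list(masks = masks, placement = do.call(rbind, placement))
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
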