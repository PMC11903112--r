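test_that("lognormal quartile calibration matches its closed form and round trips", {
  law <- fit_lognormal_from_quartiles(66.6, 50.1, 86.4)
  expect_equal(law$mu, log(66.6))
  expect_equal(law$sigma, log(86.4 / 50.1) / (2 * stats::qnorm(0.75)))
  expect_equal(law$sigma, 0.404, tolerance = 0.001)
  expect_error(fit_lognormal_from_quartiles(50, 60, 70), "q1 < median")

  # degenerate limit: quartiles collapsing onto the median drive sigma to 0
  expect_lt(fit_lognormal_from_quartiles(50, 49.999, 50.001)$sigma, 1e-4)

  # sampling round trip: quartiles of 1e5 draws within 2% of the inputs
  set.seed(53)
  draws <- stats::rlnorm(1e5, law$mu, law$sigma)
  expect_lt(abs(lob_quantile(draws, 0.5) - 66.6) / 66.6, 0.02)
  expect_lt(abs(lob_quantile(draws, 0.25) - 50.1) / 50.1, 0.02)
  expect_lt(abs(lob_quantile(draws, 0.75) - 86.4) / 86.4, 0.02)
})

test_that("rendered polygons hit the requested area exactly and the ellipse axis ratio", {
  # circle limit: regular polygon, equal Feret diameters
  s <- render_nucleus_polygon(25, 0, 0, 64, seed = 1)
  expect_equal(polygon_area(s$vertices), 25, tolerance = 1e-12)
  expect_lt(max_feret(s$vertices) / min_feret(s$vertices) - 1, 0.01)

  # eccentric ellipse: axis ratio a/b = 1/sqrt(1 - e^2) within 2%
  s9 <- render_nucleus_polygon(40, 0.9, 0, 128, seed = 2)
  ratio <- max_feret(s9$vertices) / min_feret(s9$vertices)
  expect_lt(abs(ratio - 1 / sqrt(1 - 0.81)) / (1 / sqrt(1 - 0.81)), 0.02)

  # same seed, same vertices; different seed, different rotation
  a <- render_nucleus_polygon(30, 0.5, 0.1, 96, seed = 7)
  b <- render_nucleus_polygon(30, 0.5, 0.1, 96, seed = 7)
  c_ <- render_nucleus_polygon(30, 0.5, 0.1, 96, seed = 8)
  expect_identical(a$vertices, b$vertices)
  expect_false(isTRUE(all.equal(a$vertices, c_$vertices)))

  # noisy rings stay simple and satisfy the measurement invariants
  set.seed(59)
  for (rep in 1:25) {
    s <- render_nucleus_polygon(stats::runif(1, 20, 100),
                                stats::runif(1, 0, 0.9),
                                stats::runif(1, 0, 0.45), 96)
    expect_true(lobmorph:::ring_is_simple(s$vertices))
    rec <- measure_nucleus(s)
    expect_true(rec$min_feret_um <= rec$max_feret_um)
    expect_true(rec$perimeter_um^2 >= 4 * pi * rec$area_um2)
    expect_true(rec$area_um2 <= rec$min_feret_um * rec$max_feret_um)
  }
})

test_that("synthetic_spec validates its parameter ranges", {
  expect_s3_class(synthetic_spec("pILC", log(60), 0.4), "synthetic_spec")
  expect_error(synthetic_spec("pILC", log(60), -0.1))
  expect_error(synthetic_spec("pILC", log(60), 0.4, boundary_noise = 0.6))
  expect_error(synthetic_spec("pILC", log(60), 0.4,
                              eccentricity_range = c(0.5, 1)))
  expect_error(synthetic_spec("weird", log(60), 0.4))
})

test_that("cohort simulation bookkeeping, determinism and degenerate heterogeneity", {
  specs <- list(
    synthetic_spec("pILC", log(66.6), 0.4, nuclei_per_case = 100L,
                   n_vertices = 32L),
    synthetic_spec("cILC_score1", log(34.1), 0.29, nuclei_per_case = 100L,
                   n_vertices = 32L)
  )
  sim <- simulate_cohort(specs, 5, seed = 71)
  expect_length(sim$shapes, 1000L)
  expect_equal(nrow(sim$manifest), 10L)
  expect_equal(nrow(sim$ground_truth), 10L)
  expect_true(all(sim$ground_truth$n_nuclei == 100L))

  # identical seeds give byte-identical GeoJSON
  sim2 <- simulate_cohort(specs, 5, seed = 71)
  p1 <- withr::local_tempfile(fileext = ".geojson")
  p2 <- withr::local_tempfile(fileext = ".geojson")
  write_qupath_geojson(sim$shapes, p1)
  write_qupath_geojson(sim2$shapes, p2)
  expect_identical(readLines(p1), readLines(p2))

  # zero heterogeneity: case medians scatter only by sampling error
  spec0 <- synthetic_spec("pILC", log(66.6), 0.4, case_heterogeneity = 0,
                          nuclei_per_case = 400L, n_vertices = 32L)
  sim0 <- simulate_cohort(list(spec0), 4, seed = 73)
  ms <- measure_nuclei(sim0$shapes)
  s <- summarize_cases(ms, sim0$manifest, "per_case")
  expect_lt(max(abs(s$median_area - 66.6) / 66.6), 0.1)
  expect_true(all(sim0$ground_truth$target_median_area == 66.6))
})

test_that("pooled medians of paired calibrated cohorts reproduce the published area ratio", {
  specs <- variant_synthetic_specs(nuclei_per_case = 2000L, n_vertices = 32L,
                                   case_heterogeneity = 0)
  sim <- simulate_cohort(specs[c("pILC", "cILC_score1")], 1, seed = 79)
  ms <- measure_nuclei(sim$shapes)
  pooled <- summarize_cases(ms, sim$manifest, "pooled_by_variant")
  r <- pooled$median_area[pooled$variant_label == "pILC"] /
    pooled$median_area[pooled$variant_label == "cILC_score1"]
  expect_lt(abs(r - 66.6 / 34.1) / (66.6 / 34.1), 0.1)
})

test_that("rasterization places every shape and degenerates cleanly", {
  sq <- nucleus_shape(cbind(c(0, 5, 5, 0), c(0, 0, 5, 5)), "sq")
  ras <- rasterize_cohort(list(sq), pixel_size = 1, tile_size = 64L)
  expect_length(ras$masks, 1L)
  expect_equal(sort(unique(as.vector(ras$masks[[1]]))), c(0L, 1L))
  expect_equal(nrow(ras$placement), 1L)

  empty <- rasterize_cohort(list(), pixel_size = 1, tile_size = 32L)
  expect_true(all(empty$masks[[1]] == 0L))

  big <- nucleus_shape(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)), "big")
  expect_error(rasterize_cohort(list(big), 1, tile_size = 64L), "larger than the tile")
})
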