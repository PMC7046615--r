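test_that("climate generator is deterministic and honours zero trends", {
  cfg0 <- synthetic_config(seed = 7, coarse_shape = c(16, 16),
                           trend_magnitudes = list(fut = 0))
  a <- generate_climate_grids(cfg0)
  b <- generate_climate_grids(cfg0)
  expect_identical(a, b)
  for (v in names(a$current))
    expect_equal(a$fut[[v]]$values, a$current[[v]]$values)
  cfg1 <- synthetic_config(seed = 7, coarse_shape = c(16, 16),
                           trend_magnitudes = list(fut = 1.5))
  d <- generate_climate_grids(cfg1)
  expect_equal(d$fut$clim1$values, d$current$clim1$values + 1.5)
  expect_error(synthetic_config(coarse_shape = c(0, 10)), "invalid config")
})

test_that("generated fields carry the configured spatial autocorrelation", {
  cfg <- synthetic_config(seed = 42, coarse_shape = c(64, 64),
                          autocorr_range = 8, n_climate_vars = 1)
  f <- generate_climate_grids(cfg)$current$clim1$values
  expect_lt(semivariance(f, 1), semivariance(f, 16))
})

test_that("land-cover layers share the fine frame and are reproducible", {
  cfg <- synthetic_config(seed = 5, coarse_shape = c(12, 12),
                          fine_factor = 3, n_ponds = 1)
  a <- generate_landcover_layers(cfg)
  b <- generate_landcover_layers(cfg)
  expect_identical(a$ponds, b$ponds)
  expect_equal(nrow(a$ponds), 1L)
  for (cv in a$covariates) expect_true(same_frame(cv, a$frame))
  # habitat patches cover ~10% of cells (field thresholded at 90th pct)
  covered <- sum(vapply(a$habitat_patches,
                        function(p) length(p$cells), integer(1)))
  expect_equal(covered, sum(a$covariates$lc1$values >=
                              quantile(a$covariates$lc1$values, 0.9)))
  expect_gt(covered / length(a$frame$values), 0.05)
  expect_lt(covered / length(a$frame$values), 0.15)
})

test_that("occurrence sampling tracks the true suitability surface", {
  frame9 <- grid_raster(matrix(0, 20, 20), cell_size = 50)
  # uniform suitability: quadrat counts consistent with spatial uniformity
  unif <- list(v = grid_raster(matrix(0, 20, 20), cell_size = 50))
  model <- true_suitability_model(c(v = 0), intercept = 0)  # p = 0.5 all
  occ <- sample_occurrences(model, unif, 1000, seed = 4)
  qr <- cut(occ$x, breaks = seq(0, 1000, by = 250), include.lowest = TRUE)
  qc <- cut(occ$y, breaks = seq(-1000, 0, by = 250), include.lowest = TRUE)
  counts <- as.vector(table(qr, qc))
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
  # point-mass suitability: every draw lands on that cell
  v <- matrix(-50, 5, 5); v[13] <- 50
  spike <- list(v = grid_raster(v, cell_size = 50))
  occ2 <- sample_occurrences(true_suitability_model(c(v = 1)), spike, 25,
                             seed = 1)
  expect_true(all(occ2$cell == 13))
  # n = 0 and impossible sampling
  expect_equal(nrow(sample_occurrences(model, unif, 0, seed = 1)), 0L)
  zero <- list(v = grid_raster(matrix(-Inf, 3, 3)))
  expect_error(sample_occurrences(true_suitability_model(c(v = 1)), zero,
                                  5, seed = 1), "impossible")
})

test_that("presences are biased toward suitable cells", {
  cfg <- synthetic_config(seed = 9, coarse_shape = c(32, 32),
                          n_climate_vars = 2)
  cg <- generate_climate_grids(cfg)
  model <- true_suitability_model(c(clim1 = 2, clim2 = -1), 0)
  tru <- true_suitability(model, cg$current)
  occ <- sample_occurrences(model, cg$current, 200, seed = 11)
  expect_gt(mean(tru$values[occ$cell]), mean(tru$values))
  # determinism of the sampler
  occ2 <- sample_occurrences(model, cg$current, 200, seed = 11)
  expect_identical(occ, occ2)
})
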