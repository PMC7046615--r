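test_that("the binarization threshold is the presence 10th percentile", {
  v <- matrix(seq(0.05, 1, length.out = 100), 10, 10)
  h <- grid_raster(v, cell_size = 50)
  cc <- cell_centers(h)
  # constant presence suitability -> that constant
  hc <- grid_raster(matrix(0.42, 10, 10), cell_size = 50)
  expect_equal(binarization_threshold(hc, cc[1:10, ]), 0.42)
  # presence HSI {0.1, ..., 1.0} -> 0.19 (linear interpolation)
  v[1:10] <- seq(0.1, 1, by = 0.1)
  h <- grid_raster(v, cell_size = 50)
  pres <- cell_centers(h, 1:10)
  expect_equal(binarization_threshold(h, pres), 0.19, tolerance = 1e-6)
  expect_lte(binarization_threshold(h, pres), max(v[1:10]))
  outside <- data.frame(x = -999, y = 999)
  expect_error(binarization_threshold(h, outside), "no presence")
})

test_that("patch extraction is 8-connected with mean-HSI capacity", {
  v <- matrix(0, 5, 5)
  v[1, 1] <- 0.6; v[2, 2] <- 0.6  # diagonal corner contact
  p <- extract_patches(grid_raster(v, cell_size = 50), 0.5)
  expect_length(p, 1L)
  expect_equal(p[[1]]$capacity, 0.6)
  expect_equal(p[[1]]$area, 2 * 50^2)
  # capacity is the mean HSI over member cells
  v2 <- matrix(0, 4, 4); v2[1, 1:2] <- c(0.5, 0.9)
  p2 <- extract_patches(grid_raster(v2), 0.5)
  expect_equal(p2[[1]]$capacity, 0.7)
  # component counts agree with a flood-fill oracle on random grids
  set.seed(14)
  for (i in 1:15) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    hp <- grid_raster(matrix(as.numeric(m), 20, 20))
    expect_length(extract_patches(hp, 0.5), bf_component_count(m))
  }
  # patches partition the suitable cells
  hp <- grid_raster(matrix(runif(400), 20, 20))
  pats <- extract_patches(hp, 0.6)
  cells <- unlist(lapply(pats, `[[`, "cells"))
  expect_equal(sort(cells), which(as.vector(hp$values >= 0.6)))
  expect_equal(anyDuplicated(cells), 0L)
})

test_that("the resistance transformation matches its printed endpoints", {
  thr <- 0.4
  h <- grid_raster(matrix(c(0, thr / 2, thr, 0.7, 1, 0.1), 2, 3))
  r <- resistance_surface(h, thr)
  expect_equal(r$values[1, 1], 1000)
  expect_equal(r$values[2, 1], 1000 * sqrt(0.001))  # HSI = thr/2
  expect_equal(r$values[1, 2], 1)
  expect_equal(r$values[2, 2], 1)                   # HSI above threshold
  expect_equal(r$values[1, 3], 1)
  # continuity at the threshold and monotone non-increasing in HSI
  grid <- seq(0, 1, length.out = 2001)
  rv <- resistance_surface(grid_raster(matrix(grid, 1)), thr)$values
  expect_true(all(diff(as.vector(rv)) <= 1e-9))
  expect_lt(abs(rv[which(grid >= thr)[1]] -
                  rv[which(grid >= thr)[1] - 1]), 1.2)
  expect_true(all(rv >= 1 & rv <= 1000))
  expect_error(resistance_surface(h, 0), "threshold")
})

test_that("least-cost distances match exhaustive path enumeration", {
  # straight line in uniform resistance: 10 moves of 50 m
  res <- flat_raster(1, 1, 12, cell_size = 50)
  expect_equal(least_cost_distance(res, 1L, 11L), 500)
  set.seed(15)
  for (i in 1:25) {
    nr <- sample(2:4, 1); nc <- sample(2:4, 1)
    r <- grid_raster(matrix(exp(runif(nr * nc, 0, 5)), nr, nc),
                     cell_size = 50)
    cells <- sample(nr * nc, 2)
    d <- least_cost_distance(r, cells[1], cells[2])
    expect_equal(d, bf_cost_distance(r, cells[1], cells[2]))
    # never below Euclidean distance (resistance >= 1 after max(1, .))
  }
  # cost >= Euclidean when resistance >= 1
  r1 <- grid_raster(matrix(runif(16, 1, 30), 4, 4), cell_size = 50)
  cc <- cell_centers(r1)
  d <- least_cost_distance(r1, 1L, 16L)
  eucl <- sqrt((cc$x[1] - cc$x[16])^2 + (cc$y[1] - cc$y[16])^2)
  expect_gte(d, eucl)
})

test_that("graph construction prunes edges beyond the dispersal cap", {
  # single patch: one node, no edges
  v <- matrix(0.01, 5, 5); v[3, 3] <- 0.9
  g1 <- build_graph(grid_raster(v, cell_size = 50), threshold = 0.5,
                    dispersal_dist = 1000)
  expect_length(g1$patches, 1L)
  expect_equal(nrow(g1$edges), 0L)
  expect_false(g1$no_graph)
  expect_equal(g1$alpha, -log(0.05) / 1000)
  # two suitable patches in ideal terrain: edge cost = boundary distance
  v2 <- matrix(0.9, 3, 20)  # all suitable -> resistance 1 everywhere
  v2[, 8:12] <- 0.2         # unsuitable gap splits into two patches
  h2 <- grid_raster(v2, cell_size = 50)
  g2 <- build_graph(h2, threshold = 0.5, dispersal_dist = 1e6)
  expect_length(g2$patches, 2L)
  expect_equal(nrow(g2$edges), 1L)
  # 6 moves across the 5-column gap; gap resistance for HSI 0.2/thr 0.5
  gap_res <- exp(log(0.001) * 0.2 / 0.5) * 1000
  expect_equal(g2$edges$cost, 50 * (1 + gap_res) / 2 * 2 + 50 * gap_res * 4)
  # beyond the cap: no edges
  g3 <- build_graph(h2, threshold = 0.5, dispersal_dist = 100)
  expect_equal(nrow(g3$edges), 0L)
  # zero patches: the "no graph" outcome, not an error
  g4 <- build_graph(grid_raster(matrix(0.01, 4, 4)), threshold = 0.5)
  expect_true(g4$no_graph)
  expect_length(g4$patches, 0L)
})

test_that("patch edge costs obey a relaxed triangle inequality", {
  set.seed(16)
  v <- matrix(0.05, 10, 30)
  v[4:6, 2:4] <- 0.9; v[4:6, 14:16] <- 0.9; v[4:6, 26:28] <- 0.9
  g <- build_graph(grid_raster(v, cell_size = 50), threshold = 0.5,
                   dispersal_dist = 1e9)
  expect_length(g$patches, 3L)
  d <- matrix(Inf, 3, 3); diag(d) <- 0
  for (k in seq_len(nrow(g$edges)))
    d[g$edges$i[k], g$edges$j[k]] <- d[g$edges$j[k], g$edges$i[k]] <-
      g$edges$cost[k]
  # slack: crossing the middle patch costs at most its diameter
  slack <- 50 * sqrt(2) * 10
  expect_lte(d[1, 3], d[1, 2] + d[2, 3] + slack)
})
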