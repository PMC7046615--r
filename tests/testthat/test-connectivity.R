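test_that("interaction flux matches hand values and the double-loop oracle", {
  # single patch: empty sum
  single <- synthetic_graph(0.7, matrix(0, 1, 1))
  expect_equal(interaction_flux(single)$if_values, 0)
  # two unit patches at exactly the dispersal cap: p = 0.05
  two <- synthetic_graph(c(1, 1), matrix(c(0, 1000, 1000, 0), 2, 2),
                         dispersal_dist = 1000)
  expect_equal(interaction_flux(two)$if_values, c(0.05, 0.05))
  # random graphs vs brute-force double loop
  set.seed(21)
  for (i in 1:20) {
    n <- sample(2:12, 1)
    a <- runif(n, 0.1, 1)
    d <- matrix(runif(n * n, 0, 2500), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    g <- synthetic_graph(a, d, dispersal_dist = 1000)
    expect_equal(interaction_flux(g)$if_values,
                 bf_interaction_flux(a, d, g$alpha, 1000))
  }
})

test_that("interaction flux is monotone in capacities and distances", {
  set.seed(22)
  n <- 8
  a <- runif(n, 0.2, 0.9)
  d <- matrix(runif(n * n, 100, 900), n, n); d <- (d + t(d)) / 2; diag(d) <- 0
  base <- interaction_flux(synthetic_graph(a, d))$if_values
  # raising one capacity never decreases any IF
  a2 <- a; a2[3] <- a2[3] + 0.1
  up <- interaction_flux(synthetic_graph(a2, d))$if_values
  expect_true(all(up >= base - 1e-12))
  # increasing one distance never increases the flux of its endpoints
  d2 <- d; d2[1, 2] <- d2[2, 1] <- d2[1, 2] + 300
  further <- interaction_flux(synthetic_graph(a, d2))$if_values
  expect_lte(further[1], base[1] + 1e-12)
  expect_lte(further[2], base[2] + 1e-12)
})

test_that("interpolation recovers patch values and zeroes beyond the cap", {
  # outside HSI 0.45 under threshold 0.5 -> resistance ~2, so cost grows
  # ~100 per cell: cols 13..20 of row 11 are within an 800 m cap, col 21 not
  v <- matrix(0.45, 21, 21); v[10:12, 10:12] <- 0.9
  h <- grid_raster(v, cell_size = 50)
  g <- build_graph(h, threshold = 0.5, dispersal_dist = 800)
  ifr <- interaction_flux(g)
  # give the single patch a nonzero flux to interpolate
  ifr$if_values <- 0.8
  m <- interpolate_metric(ifr)
  expect_equal(m$raster$values[11, 11], 0.8)  # inside the patch
  expect_equal(m$raster$values[10, 10], 0.8)  # boundary cell
  # within range the single-patch weighted mean equals its IF, then 0
  prof <- m$raster$values[11, 13:21]
  expect_true(all(abs(prof[1:7] - 0.8) < 1e-12))
  expect_equal(prof[9], 0)
  expect_equal(m$raster$values[1, 21], 0)  # far corner beyond the cap
  # constant IF over several patches: every within-range cell equals it
  v2 <- matrix(0.9, 5, 12); v2[, 6:7] <- 0.55
  h2 <- grid_raster(v2, cell_size = 50)
  g2 <- build_graph(h2, threshold = 0.6, dispersal_dist = 5000)
  if2 <- interaction_flux(g2)
  if2$if_values <- rep(0.3, length(g2$patches))
  m2 <- interpolate_metric(if2)
  expect_true(all(abs(m2$raster$values - 0.3) < 1e-12))
  # with unequal fluxes every interpolated value stays between them
  if3 <- interaction_flux(g2)
  if3$if_values <- c(0.2, 0.6)
  m3 <- interpolate_metric(if3)
  expect_true(all(m3$raster$values >= 0.2 - 1e-12 &
                    m3$raster$values <= 0.6 + 1e-12))
})

test_that("normalization yields z-scores invariant to affine inputs", {
  v <- matrix(c(0, 2, 1, 3, 5, 1), 2, 3)
  m <- connectivity_map(grid_raster(v))
  z <- normalize_map(m)
  expect_equal(mean(z$raster$values), 0)
  expect_equal(sqrt(mean(z$raster$values^2)), 1)  # population sd
  m_aff <- connectivity_map(grid_raster(3 * v + 7))
  expect_equal(normalize_map(m_aff)$raster$values, z$raster$values)
  two <- normalize_map(connectivity_map(grid_raster(matrix(c(0, 2), 1))))
  expect_equal(as.vector(two$raster$values), c(-1, 1))
  const <- connectivity_map(grid_raster(matrix(1, 2, 2)))
  expect_error(normalize_map(const), "constant")
})

test_that("species combination averages normalized maps cellwise", {
  set.seed(23)
  mk <- function(v) normalize_map(connectivity_map(grid_raster(v)))
  a <- mk(matrix(rnorm(16), 4, 4))
  b <- mk(matrix(rnorm(16), 4, 4))
  comb <- combine_species(list(a, b))
  expect_equal(comb$raster$values,
               (a$raster$values + b$raster$values) / 2)
  expect_equal(combine_species(list(a, a))$raster$values, a$raster$values)
  neg <- a; neg$raster$values <- -a$raster$values
  expect_equal(combine_species(list(a, neg))$raster$values,
               matrix(0, 4, 4))
  raw <- connectivity_map(grid_raster(matrix(rnorm(16), 4, 4)))
  expect_error(combine_species(list(a, raw)), "normalized")
  small <- mk(matrix(rnorm(4), 2, 2))
  expect_error(combine_species(list(a, small)), "frame")
})

test_that("scenario difference maps are antisymmetric", {
  mk <- function(v) normalize_map(connectivity_map(grid_raster(v)))
  set.seed(24)
  cur <- mk(matrix(rnorm(16), 4, 4))
  fut <- mk(matrix(rnorm(16), 4, 4))
  expect_equal(delta_map(cur, cur)$values, matrix(0, 4, 4))
  expect_equal(delta_map(fut, cur)$values, -delta_map(cur, fut)$values)
  raw <- connectivity_map(grid_raster(matrix(rnorm(16), 4, 4)))
  expect_error(delta_map(fut, raw), "normalization")
})
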