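#' Habitat suitability index surface
#'
#' Cellwise product of climate-only and land-cover-only ensemble outputs,
#' in [0, 1], carrying species and scenario labels.
#'
#' @param raster `grid_raster` of HSI values.
#' @param species,scenario Labels.
#' @return An object of class `hsi_surface`.
#' @export
hsi_surface <- function(raster, species = "species", scenario = "current") {
  stopifnot_raster(raster)
  structure(list(raster = raster, species = species, scenario = scenario),
            class = "hsi_surface")
}

as_grid_raster <- function(x) {
  if (is_grid_raster(x)) x
  else if (inherits(x, "hsi_surface")) x$raster
  else if (inherits(x, "connectivity_map")) x$raster
  else stop("cannot interpret object as a raster", call. = FALSE)
}

#' Combine climate and land-cover suitability into an HSI
#'
#' Multiplies the (disaggregated) climate-only probability surface with the
#' land-cover-only probability surface, assuming independent effects.
#' Future-scenario HSI pairs a future climate surface with the *current*
#' land-cover surface (no land-cover change assumed in the future).
#'
#' @param climate `grid_raster` of climate suitability on the fine frame.
#' @param landcover `grid_raster` of land-cover suitability (fine frame).
#' @param species,scenario Labels attached to the result.
#' @return An `hsi_surface`.
#' @export
combine_suitability <- function(climate, landcover, species = "species",
                                scenario = "current") {
  climate <- as_grid_raster(climate); landcover <- as_grid_raster(landcover)
  check_same_frame(climate, landcover, "climate and land-cover surfaces")
  hsi_surface(grid_raster(climate$values * landcover$values,
                          climate$origin, climate$cell_size, climate$crs),
              species = species, scenario = scenario)
}

#' Total suitable area
#'
#' Area (km^2) of the cells whose HSI is at or above a threshold.
#'
#' @param hsi An `hsi_surface` or `grid_raster`.
#' @param threshold Suitability threshold in [0, 1].
#' @return Area in km^2.
#' @export
suitable_area <- function(hsi, threshold) {
  r <- as_grid_raster(hsi)
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  sum(r$values >= threshold, na.rm = TRUE) * r$cell_size^2 / 1e6
}

#' Global Moran's I
#'
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`
#' with `W` the total weight. Bounded in [-1, 1] for row-standardized
#' weights; 0 indicates a random spatial pattern.
#'
#' @param values Numeric vector (>= 3, non-constant).
#' @param weights n x n spatial weight matrix (diagonal ignored).
#' @return Moran's I.
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  if (n < 3L) stop("need >= 3 locations", call. = FALSE)
  w <- as.matrix(weights)
  if (!all(dim(w) == n))
    stop("`weights` must be an n x n matrix", call. = FALSE)
  diag(w) <- 0
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0)
    stop("Moran's I undefined for constant values", call. = FALSE)
  (n / sum(w)) * as.numeric(z %*% w %*% z) / denom
}

#' Permutation test for Moran's I
#'
#' Two-sided permutation test: values are randomly reassigned to locations
#' and `p = (1 + #{|I_perm| >= |I_obs|}) / (n_perm + 1)`.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List with `i` and `p_value`.
#' @export
morans_i_test <- function(values, weights, n_perm = 999L, seed = 1L) {
  i_obs <- morans_i(values, weights)
  n <- length(values)
  w <- as.matrix(weights); diag(w) <- 0
  w_sum <- sum(w)
  denom_stat <- function(x) {
    z <- x - mean(x)
    (n / w_sum) * as.numeric(z %*% w %*% z) / sum(z^2)
  }
  i_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) denom_stat(sample(values)),
           numeric(1))
  })
  p <- (1 + sum(abs(i_perm) >= abs(i_obs))) / (n_perm + 1)
  list(i = i_obs, p_value = p)
}

#' Inverse-distance spatial weights
#'
#' `w_ij = 1 / d_ij` among point locations, optionally row-standardized.
#' Duplicate locations (zero distance) are rejected.
#'
#' @param xy data.frame / matrix with `x`, `y` columns.
#' @param row_standardize Divide each row by its sum (default TRUE).
#' @return An n x n weight matrix with zero diagonal.
#' @export
inverse_distance_weights <- function(xy, row_standardize = TRUE) {
  xy <- as.data.frame(xy)
  d <- as.matrix(stats::dist(xy[, c("x", "y")]))
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate locations give infinite inverse-distance weights",
         call. = FALSE)
  w <- 1 / d
  diag(w) <- 0
  if (row_standardize) w <- w / rowSums(w)
  w
}

#' Rook-adjacency weights on a grid
#'
#' Binary 4-neighbour adjacency for the cells of an `n_row x n_col` grid in
#' row-major order, optionally row-standardized.
#'
#' @param n_row,n_col Grid dimensions.
#' @param row_standardize Divide each row by its sum (default TRUE).
#' @return An (n_row n_col) x (n_row n_col) weight matrix.
#' @export
rook_weights <- function(n_row, n_col, row_standardize = TRUE) {
  n <- n_row * n_col
  w <- matrix(0, n, n)
  id <- function(r, c) (r - 1L) * n_col + c
  for (r in seq_len(n_row)) for (c in seq_len(n_col)) {
    if (c < n_col) { w[id(r, c), id(r, c + 1L)] <- 1; w[id(r, c + 1L), id(r, c)] <- 1 }
    if (r < n_row) { w[id(r, c), id(r + 1L, c)] <- 1; w[id(r + 1L, c), id(r, c)] <- 1 }
  }
  if (row_standardize) w <- w / rowSums(w)
  w
}

#' Moran residual diagnostic of an HSI map
#'
#' Residual at each occurrence cell is `1 - HSI` (observed presence minus
#' predicted index); spatial autocorrelation of these residuals is tested
#' with Moran's I under inverse-distance row-standardized weights.
#'
#' @param hsi An `hsi_surface` or `grid_raster`.
#' @param occ Occurrence data.frame with `x`, `y` (deduplicated by cell).
#' @param n_perm Permutations for the test.
#' @param seed Integer seed.
#' @return List with `i`, `p_value`, `n` (occurrence cells used).
#' @export
hsi_residual_moran <- function(hsi, occ, n_perm = 999L, seed = 1L) {
  r <- as_grid_raster(hsi)
  cells <- xy_to_cell(r, occ$x, occ$y)
  keep <- !duplicated(cells$cell) & !is.na(cells$cell)
  cc <- cell_centers(r, cells$cell[keep])
  vals <- r$values[cc$cell]
  ok <- !is.na(vals)
  resid <- 1 - vals[ok]
  w <- inverse_distance_weights(cc[ok, c("x", "y")])
  res <- morans_i_test(resid, w, n_perm = n_perm, seed = seed)
  res$n <- sum(ok)
  res
}
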