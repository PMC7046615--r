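#' Synthetic study-area configuration
#'
#' Desk-scale analogue of a pond-breeding-amphibian study area: a coarse
#' climate grid and a fine land-cover grid nested inside it, pond points,
#' habitat polygons, and additive "future climate" scenarios. Defaults give
#' a 64 x 64 coarse grid of 200 m cells with a nested 50 m fine grid
#' (fine_factor 4), the same coarse/fine pairing idea as a 1 km climate grid
#' over a 50 m land-cover grid, shrunk so every stage runs in seconds.
#'
#' @param seed Integer; all generators are pure functions of (config, seed).
#' @param coarse_shape `(rows, cols)` of the coarse climate grid.
#' @param fine_factor Fine cells per coarse cell side (>= 1).
#' @param n_climate_vars,n_landcover_vars Number of synthetic variables.
#' @param autocorr_range Autocorrelation range of the random fields, in
#'   coarse cells.
#' @param n_ponds Number of pond points on the fine grid.
#' @param trend_magnitudes Named list, scenario -> additive shift (in field
#'   standard deviations) applied to every climate variable; analogues of
#'   low/high warming pathways.
#' @param n_presences Number of occurrence points sampled from the true
#'   suitability surface.
#' @param fine_cell_size Fine cell edge length in metres.
#' @param origin Top-left corner of the shared frame.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             coarse_shape = c(64L, 64L),
                             fine_factor = 4L,
                             n_climate_vars = 3L,
                             n_landcover_vars = 3L,
                             autocorr_range = 8,
                             n_ponds = 80L,
                             trend_magnitudes = list(rcp26_2050 = 0.75,
                                                     rcp85_2100 = 2.5),
                             n_presences = 300L,
                             fine_cell_size = 50,
                             origin = c(0, 0)) {
  cfg <- list(seed = as.integer(seed),
              coarse_shape = as.integer(coarse_shape),
              fine_factor = as.integer(fine_factor),
              n_climate_vars = as.integer(n_climate_vars),
              n_landcover_vars = as.integer(n_landcover_vars),
              autocorr_range = autocorr_range,
              n_ponds = as.integer(n_ponds),
              trend_magnitudes = trend_magnitudes,
              n_presences = as.integer(n_presences),
              fine_cell_size = fine_cell_size,
              origin = as.numeric(origin))
  if (length(cfg$coarse_shape) != 2L || any(cfg$coarse_shape <= 0) ||
      anyNA(cfg$coarse_shape))
    stop("invalid config: `coarse_shape` must be two positive integers",
         call. = FALSE)
  if (cfg$fine_factor < 1L)
    stop("invalid config: `fine_factor` must be >= 1", call. = FALSE)
  counts <- c(cfg$n_climate_vars, cfg$n_landcover_vars, cfg$n_ponds,
              cfg$n_presences)
  if (any(counts < 0) || anyNA(counts))
    stop("invalid config: counts must be >= 0", call. = FALSE)
  if (cfg$autocorr_range <= 0)
    stop("invalid config: `autocorr_range` must be positive", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

coarse_frame <- function(config) {
  grid_raster(matrix(0, config$coarse_shape[1], config$coarse_shape[2]),
              origin = config$origin,
              cell_size = config$fine_cell_size * config$fine_factor)
}

fine_frame <- function(config) {
  grid_raster(matrix(0, config$coarse_shape[1] * config$fine_factor,
                     config$coarse_shape[2] * config$fine_factor),
              origin = config$origin, cell_size = config$fine_cell_size)
}

#' Spatially autocorrelated Gaussian random field
#'
#' Gaussian-filter synthesis: white noise is convolved (via FFT, on a torus)
#' with an isotropic Gaussian kernel of standard deviation
#' `autocorr_range / 2` cells, then standardized to mean 0, sd 1. Draws from
#' the current RNG stream.
#'
#' @param nrow,ncol Field dimensions (cells).
#' @param autocorr_range Correlation range in cells.
#' @return A standardized numeric matrix.
#' @export
gaussian_random_field <- function(nrow, ncol, autocorr_range) {
  if (nrow <= 0 || ncol <= 0)
    stop("invalid config: non-positive field shape", call. = FALSE)
  noise <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (nrow * ncol == 1L) return(noise)
  sigma <- autocorr_range / 2
  dr <- pmin(0:(nrow - 1), nrow - 0:(nrow - 1))
  dc <- pmin(0:(ncol - 1), ncol - 0:(ncol - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) /
    (nrow * ncol)
  (f - mean(f)) / stats::sd(f)
}

#' Generate coarse climate grids for all scenarios
#'
#' One spatially autocorrelated standardized field per climate variable
#' under current conditions; each future scenario adds its configured
#' additive trend to every variable (land cover is assumed unchanged in the
#' future, so only climate shifts).
#'
#' @param config A `synthetic_config`.
#' @return Named list of scenarios (`current` first), each a named list of
#'   `grid_raster` climate variables (`clim1`, `clim2`, ...).
#' @export
generate_climate_grids <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  frame <- coarse_frame(config)
  nr <- nrow(frame$values); nc <- ncol(frame$values)
  current <- with_seed(config$seed, {
    lapply(seq_len(config$n_climate_vars), function(i)
      grid_raster(gaussian_random_field(nr, nc, config$autocorr_range),
                  origin = frame$origin, cell_size = frame$cell_size))
  })
  names(current) <- paste0("clim", seq_len(config$n_climate_vars))
  out <- list(current = current)
  for (sc in names(config$trend_magnitudes)) {
    shift <- rep_len(as.numeric(config$trend_magnitudes[[sc]]),
                     config$n_climate_vars)
    out[[sc]] <- lapply(seq_along(current), function(i) {
      r <- current[[i]]
      r$values <- r$values + shift[i]
      r
    })
    names(out[[sc]]) <- names(current)
  }
  out
}

#' Generate fine-grid land-cover layers
#'
#' Autocorrelated covariate fields on the fine grid, a uniform random pond
#' point set, habitat patches (8-connected components of the first
#' land-cover field thresholded at its 90th percentile), plus the derived
#' pond-distance covariate. All layers share the fine frame.
#'
#' @param config A `synthetic_config`.
#' @return List with `covariates` (named `grid_raster` list, including
#'   `dist_pond` when ponds exist), `ponds` (data.frame x, y),
#'   `habitat_patches` (list of cell-based `patch_geometry`), and `frame`.
#' @export
generate_landcover_layers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  frame <- fine_frame(config)
  nr <- nrow(frame$values); nc <- ncol(frame$values)
  rng_fine <- config$autocorr_range * config$fine_factor
  res <- with_seed(config$seed + 1L, {
    covs <- lapply(seq_len(config$n_landcover_vars), function(i)
      grid_raster(gaussian_random_field(nr, nc, rng_fine),
                  origin = frame$origin, cell_size = frame$cell_size))
    ext <- c(frame$origin[1], frame$origin[1] + nc * frame$cell_size,
             frame$origin[2] - nr * frame$cell_size, frame$origin[2])
    ponds <- data.frame(x = stats::runif(config$n_ponds, ext[1], ext[2]),
                        y = stats::runif(config$n_ponds, ext[3], ext[4]))
    list(covs = covs, ponds = ponds)
  })
  covs <- res$covs
  names(covs) <- paste0("lc", seq_len(config$n_landcover_vars))
  habitat <- list()
  if (config$n_landcover_vars >= 1L) {
    v <- covs[[1]]$values
    thr <- stats::quantile(v, 0.9, names = FALSE)
    mask <- v >= thr
    comps <- label_components(mask)
    habitat <- lapply(comps, patch_from_cells, frame = frame)
  }
  if (config$n_ponds > 0L) {
    covs$dist_pond <- distance_to_nearest(res$ponds, frame)
  } else {
    warning("n_ponds = 0: pond-distance layer is everywhere infinite",
            call. = FALSE)
  }
  list(covariates = covs, ponds = res$ponds, habitat_patches = habitat,
       frame = frame)
}

#' True suitability model (synthetic ground truth)
#'
#' Logistic link on a linear combination of covariates; used to sample
#' occurrences and, later, to score parameter recovery of the ensembles.
#'
#' @param coefficients Named numeric vector of per-variable weights (names
#'   must match covariate names).
#' @param intercept Intercept on the logit scale.
#' @return An object of class `true_suitability_model`.
#' @export
true_suitability_model <- function(coefficients, intercept = 0) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients))))
    stop("`coefficients` must be named after covariates", call. = FALSE)
  structure(list(coefficients = coefficients, intercept = intercept,
                 link = "logistic"),
            class = "true_suitability_model")
}

#' Evaluate true suitability over covariate rasters
#'
#' @param model A `true_suitability_model`.
#' @param covariates Named list of aligned `grid_raster` layers.
#' @return A `grid_raster` of probabilities in [0, 1].
#' @export
true_suitability <- function(model, covariates) {
  stopifnot(inherits(model, "true_suitability_model"))
  vars <- names(model$coefficients)
  missing <- setdiff(vars, names(covariates))
  if (length(missing))
    stop("covariates missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  frame <- covariates[[vars[1]]]
  eta <- matrix(model$intercept, nrow(frame$values), ncol(frame$values))
  for (v in vars) {
    check_same_frame(frame, covariates[[v]], "covariates")
    eta <- eta + model$coefficients[[v]] * covariates[[v]]$values
  }
  grid_raster(stats::plogis(eta), origin = frame$origin,
              cell_size = frame$cell_size, crs = frame$crs)
}

#' Sample occurrence points from a true suitability surface
#'
#' Cells are drawn (with replacement) with probability proportional to true
#' suitability; each draw is reported at its cell centre. Presences are
#' therefore biased toward suitable cells, as real survey records are.
#'
#' @param true_model A `true_suitability_model`.
#' @param covariates Named list of aligned `grid_raster` layers.
#' @param n Number of points.
#' @param seed Integer seed.
#' @param species Species label attached to the output.
#' @return data.frame with `species`, `x`, `y`, `cell`.
#' @export
sample_occurrences <- function(true_model, covariates, n, seed,
                               species = "species") {
  p_r <- true_suitability(true_model, covariates)
  p <- as.vector(p_r$values)
  p[is.na(p)] <- 0
  if (n > 0 && sum(p) <= 0)
    stop("sampling impossible: true suitability is zero everywhere",
         call. = FALSE)
  if (n == 0)
    return(data.frame(species = character(0), x = numeric(0),
                      y = numeric(0), cell = integer(0)))
  cells <- with_seed(seed,
    sample.int(length(p), size = n, replace = TRUE, prob = p))
  cc <- cell_centers(p_r, cells)
  data.frame(species = species, x = cc$x, y = cc$y, cell = cc$cell)
}

# 8-connected component labelling of a logical matrix.
# Returns a list of integer cell-index vectors, ordered by the row-major
# position of each component's first cell.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask)
  if (!length(cells)) return(list())
  pos <- integer(nr * nc)
  pos[cells] <- seq_along(cells)
  np <- neighbor_pairs(nr, nc, diagonal = TRUE)
  keep <- mask[np$from] & mask[np$to]
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(pos[np$from[keep]], pos[np$to[keep]]))
  memb <- igraph::components(g)$membership
  comps <- split(cells, memb)
  # deterministic order: row-major index of each component's first cell
  key <- vapply(comps, function(cl) {
    r <- ((cl - 1L) %% nr) + 1L
    c <- ((cl - 1L) %/% nr) + 1L
    min((r - 1L) * nc + c)
  }, numeric(1))
  unname(comps[order(key)])
}
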