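#' Binarization threshold from training presences
#'
#' The 10th percentile (linear-interpolation definition, `quantile type 7`)
#' of the HSI values at the training presence cells. Removes the bottom 10%
#' of occupied suitability values, which may reflect data errors or sink
#' populations.
#'
#' @param hsi An `hsi_surface` or `grid_raster`.
#' @param presences data.frame with `x`, `y` of training presences.
#' @param percentile Percentile in [0, 1] (default 0.1).
#' @return The threshold value.
#' @export
binarization_threshold <- function(hsi, presences, percentile = 0.1) {
  r <- as_grid_raster(hsi)
  vals <- raster_extract(r, presences$x, presences$y)
  vals <- vals[!is.na(vals)]
  if (!length(vals))
    stop("no presence falls on a valid cell", call. = FALSE)
  stats::quantile(vals, percentile, names = FALSE, type = 7)
}

#' Extract habitat patches from an HSI surface
#'
#' 8-connected components of the cells with `HSI >= threshold`. Each patch
#' carries its cells, its area and its capacity (mean HSI over its cells, a
#' proxy for demographic potential). Patch ids follow the row-major position
#' of each patch's first cell, so extraction is deterministic.
#'
#' @inheritParams binarization_threshold
#' @param threshold Suitability threshold in [0, 1].
#' @return List of patches, each `list(id, cells, area, capacity)`. May be
#'   empty (no suitable cell).
#' @export
extract_patches <- function(hsi, threshold) {
  r <- as_grid_raster(hsi)
  if (threshold < 0 || threshold > 1)
    stop("`threshold` must be in [0, 1]", call. = FALSE)
  mask <- !is.na(r$values) & r$values >= threshold
  comps <- label_components(mask)
  lapply(seq_along(comps), function(i) {
    cells <- comps[[i]]
    list(id = i, cells = cells, area = length(cells) * r$cell_size^2,
         capacity = mean(r$values[cells]))
  })
}

#' Resistance surface from an HSI
#'
#' Movement resistance is 1 inside suitable habitat (`HSI >= threshold`)
#' and `exp(ln(0.001) * HSI / threshold) * 1000` below it: an exponential
#' ramp that is continuous at the threshold and reaches 1000 where HSI = 0.
#' The surface therefore ranges over [1, 1000].
#'
#' @inheritParams extract_patches
#' @param threshold Suitability threshold in (0, 1].
#' @return A `grid_raster` of resistance values.
#' @export
resistance_surface <- function(hsi, threshold) {
  r <- as_grid_raster(hsi)
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  v <- r$values
  out <- ifelse(v >= threshold, 1, exp(log(0.001) * v / threshold) * 1000)
  out[is.na(v)] <- NA
  grid_raster(out, r$origin, r$cell_size, r$crs)
}

# Weighted 8-neighbour grid graph over a resistance raster.
# Moving between adjacent cells costs cell_size x mean incident resistance,
# x sqrt(2) for diagonal moves; edges touching nodata are dropped.
grid_cost_graph <- function(resistance) {
  stopifnot_raster(resistance)
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v)
  np <- neighbor_pairs(nr, nc, diagonal = TRUE)
  ok <- !is.na(v[np$from]) & !is.na(v[np$to])
  from <- np$from[ok]; to <- np$to[ok]; dg <- np$diag[ok]
  w <- resistance$cell_size * (v[from] + v[to]) / 2 * ifelse(dg, sqrt(2), 1)
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  g
}

# Append one zero-cost virtual vertex per patch, wired to its member cells.
# Returns list(graph, vids) with vids the virtual vertex ids.
graph_with_patch_nodes <- function(g, patches) {
  ncell <- igraph::vcount(g)
  g2 <- igraph::add_vertices(g, length(patches))
  vids <- ncell + seq_along(patches)
  for (i in seq_along(patches)) {
    cells <- patches[[i]]$cells
    g2 <- igraph::add_edges(g2, rbind(rep(vids[i], length(cells)), cells),
                            weight = 0)
  }
  list(graph = g2, vids = vids)
}

#' Least-cost distance between two patches
#'
#' Minimum over source-cell to target-cell paths of the accumulated move
#' cost on the resistance surface (multi-source shortest-path search).
#' Because resistance is >= 1, the result is never below the Euclidean
#' distance between the patch boundaries. `Inf` signals patches separated
#' by nodata.
#'
#' @param resistance `grid_raster` of resistance values.
#' @param source,target Patches (as returned by [extract_patches()]) or
#'   plain vectors of linear cell indices.
#' @return Cost distance (metre-equivalent units at resistance 1).
#' @export
least_cost_distance <- function(resistance, source, target) {
  src <- if (is.list(source)) source$cells else as.integer(source)
  tgt <- if (is.list(target)) target$cells else as.integer(target)
  if (!length(src) || !length(tgt))
    stop("patches must be non-empty", call. = FALSE)
  g <- grid_cost_graph(resistance)
  d <- igraph::distances(g, v = src, to = tgt, algorithm = "dijkstra")
  min(d)
}

# All-pairs patch cost-distance matrix via virtual patch vertices.
patch_cost_matrix <- function(resistance, patches, graph = NULL) {
  if (!length(patches)) return(matrix(numeric(0), 0, 0))
  g <- if (is.null(graph)) grid_cost_graph(resistance) else graph
  gp <- graph_with_patch_nodes(g, patches)
  d <- igraph::distances(gp$graph, v = gp$vids, to = gp$vids,
                         algorithm = "dijkstra")
  dimnames(d) <- NULL
  d
}

#' Build a landscape graph from an HSI surface
#'
#' The five-to-four step bridge: threshold the HSI (10th percentile of
#' training presences unless given), extract 8-connected habitat patches
#' with capacities, derive the resistance surface, compute least-cost
#' distances between all patch pairs, and keep the edges within the
#' dispersal cap. Because resistance is 1 inside suitable habitat, cost
#' units coincide with metres in ideal terrain, and the dispersal cap is
#' applied directly in cost units. The interaction-probability decay rate
#' `alpha = -ln(0.05) / dispersal_dist` (probability 0.05 at the cap) is
#' stored on the graph.
#'
#' @inheritParams binarization_threshold
#' @param presences Training presences (needed when `threshold` is NULL).
#' @param dispersal_dist Maximum dispersal distance (cost units ~ m),
#'   default 1000.
#' @param threshold Optional explicit threshold in (0, 1].
#' @param percentile Presence percentile when deriving the threshold.
#' @return An object of class `landscape_graph`; with zero patches an empty
#'   graph is returned (the "no graph" outcome), not an error.
#' @export
build_graph <- function(hsi, presences = NULL, dispersal_dist = 1000,
                        threshold = NULL, percentile = 0.1) {
  r <- as_grid_raster(hsi)
  if (is.null(threshold)) {
    if (is.null(presences))
      stop("supply `presences` or an explicit `threshold`", call. = FALSE)
    threshold <- binarization_threshold(r, presences, percentile)
  }
  alpha <- -log(0.05) / dispersal_dist
  patches <- if (threshold > 0) extract_patches(r, threshold) else list()
  if (threshold <= 0 || !length(patches)) {
    return(structure(list(patches = list(),
                          edges = data.frame(i = integer(0), j = integer(0),
                                             cost = numeric(0)),
                          threshold = threshold, alpha = alpha,
                          dispersal_dist = dispersal_dist,
                          resistance = NULL, frame = r,
                          no_graph = TRUE),
                     class = "landscape_graph"))
  }
  resistance <- resistance_surface(r, threshold)
  d <- patch_cost_matrix(resistance, patches)
  n <- length(patches)
  edges <- data.frame(i = integer(0), j = integer(0), cost = numeric(0))
  if (n > 1L) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    cost <- d[idx]
    keep <- is.finite(cost) & cost <= dispersal_dist
    edges <- data.frame(i = idx[keep, 1], j = idx[keep, 2],
                        cost = cost[keep])
  }
  structure(list(patches = patches, edges = edges, threshold = threshold,
                 alpha = alpha, dispersal_dist = dispersal_dist,
                 resistance = resistance, frame = r, no_graph = FALSE),
            class = "landscape_graph")
}

#' @export
print.landscape_graph <- function(x, ...) {
  if (x$no_graph)
    cat(sprintf("<landscape_graph> no habitat patch at threshold %.4g\n",
                x$threshold))
  else
    cat(sprintf(
      "<landscape_graph> %d patches, %d edges (<= %g cost units), threshold %.4g\n",
      length(x$patches), nrow(x$edges), x$dispersal_dist, x$threshold))
  invisible(x)
}

#' Patch attribute table
#'
#' @param graph A `landscape_graph`.
#' @return data.frame with `id`, `n_cells`, `area_m2`, `capacity`.
#' @export
patch_table <- function(graph) {
  stopifnot(inherits(graph, "landscape_graph"))
  if (!length(graph$patches))
    return(data.frame(id = integer(0), n_cells = integer(0),
                      area_m2 = numeric(0), capacity = numeric(0)))
  data.frame(
    id = vapply(graph$patches, `[[`, integer(1), "id"),
    n_cells = vapply(graph$patches, function(p) length(p$cells), integer(1)),
    area_m2 = vapply(graph$patches, `[[`, numeric(1), "area"),
    capacity = vapply(graph$patches, `[[`, numeric(1), "capacity"))
}

#' Label raster of patch membership
#'
#' @param graph A `landscape_graph`.
#' @return A `grid_raster` with patch ids (NA outside patches).
#' @export
patch_raster <- function(graph) {
  stopifnot(inherits(graph, "landscape_graph"))
  f <- graph$frame
  lab <- matrix(NA_real_, nrow(f$values), ncol(f$values))
  for (p in graph$patches) lab[p$cells] <- p$id
  grid_raster(lab, f$origin, f$cell_size, f$crs)
}

#' Serialize a landscape graph to JSON
#'
#' Documented bundle: threshold, alpha, dispersal cap, patch table and edge
#' list (the resistance raster travels separately as a grid file).
#'
#' @param graph A `landscape_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "landscape_graph"))
  bundle <- list(threshold = graph$threshold, alpha = graph$alpha,
                 dispersal_dist = graph$dispersal_dist,
                 no_graph = graph$no_graph,
                 patches = patch_table(graph), edges = graph$edges)
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
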