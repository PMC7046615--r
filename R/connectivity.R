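#' Interaction flux of every habitat patch
#'
#' `IF_i = sum_{j != i} a_i a_j p_ij` where `a` are patch capacities and
#' `p_ij = exp(-alpha d_ij)` the interaction probability over the graph's
#' retained edges (`p_ij = 0` for pruned pairs). The per-patch contribution
#' to global connectivity: 0 for an isolated (or single) patch, bounded by
#' `a_i * sum_j a_j`.
#'
#' @param graph A `landscape_graph`.
#' @return An object of class `if_result` with per-patch `if_values`.
#' @export
interaction_flux <- function(graph) {
  stopifnot(inherits(graph, "landscape_graph"))
  n <- length(graph$patches)
  if_values <- numeric(n)
  if (n > 1L && nrow(graph$edges)) {
    a <- vapply(graph$patches, `[[`, numeric(1), "capacity")
    p <- exp(-graph$alpha * graph$edges$cost)
    contrib <- a[graph$edges$i] * a[graph$edges$j] * p
    for (k in seq_len(nrow(graph$edges))) {
      if_values[graph$edges$i[k]] <- if_values[graph$edges$i[k]] + contrib[k]
      if_values[graph$edges$j[k]] <- if_values[graph$edges$j[k]] + contrib[k]
    }
  }
  structure(list(if_values = if_values, alpha = graph$alpha, graph = graph),
            class = "if_result")
}

#' Connectivity map
#'
#' A raster of (possibly interpolated, possibly normalized) connectivity
#' values with species / scenario labels.
#'
#' @param raster A `grid_raster`.
#' @param species,scenario Labels.
#' @param normalized Whether values are z-scores.
#' @return An object of class `connectivity_map`.
#' @export
connectivity_map <- function(raster, species = "species",
                             scenario = "current", normalized = FALSE) {
  stopifnot_raster(raster)
  structure(list(raster = raster, species = species, scenario = scenario,
                 normalized = normalized),
            class = "connectivity_map")
}

#' Interpolate the interaction flux across the landscape
#'
#' Cells inside a patch take that patch's IF. Outside, the value is the
#' weighted mean of the IF of every patch within the dispersal cap (in cost
#' distance from the patch), with decreasing weights
#' `exp(-alpha * costdist)`; cells beyond the cap of every patch get 0.
#' The weighted *mean* (not sum) recovers a patch's own value at its edge.
#'
#' @param if_result An `if_result` from [interaction_flux()].
#' @param species,scenario Labels for the output map.
#' @return A `connectivity_map` on the graph's frame.
#' @export
interpolate_metric <- function(if_result, species = "species",
                               scenario = "current") {
  stopifnot(inherits(if_result, "if_result"))
  graph <- if_result$graph
  f <- graph$frame
  out <- matrix(0, nrow(f$values), ncol(f$values))
  out[is.na(f$values)] <- NA
  if (length(graph$patches)) {
    g <- grid_cost_graph(graph$resistance)
    gp <- graph_with_patch_nodes(g, graph$patches)
    d <- igraph::distances(gp$graph, v = gp$vids,
                           to = seq_len(length(f$values)),
                           algorithm = "dijkstra")
    w <- exp(-if_result$alpha * d)
    w[!is.finite(d) | d > graph$dispersal_dist] <- 0
    wsum <- colSums(w)
    num <- colSums(w * if_result$if_values)
    vals <- ifelse(wsum > 0, num / wsum, 0)
    out[] <- vals
    for (p in graph$patches) out[p$cells] <- if_result$if_values[p$id]
    out[is.na(graph$resistance$values)] <- NA
  }
  connectivity_map(grid_raster(out, f$origin, f$cell_size, f$crs),
                   species = species, scenario = scenario)
}

#' z-normalize a connectivity map
#'
#' Centres and scales the valid cells to mean 0 and (population) standard
#' deviation 1, making IF maps from different graphs comparable before
#' cross-species combination.
#'
#' @param map A `connectivity_map`.
#' @return The normalized `connectivity_map`.
#' @export
normalize_map <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  v <- map$raster$values
  ok <- !is.na(v)
  mu <- mean(v[ok])
  sd_pop <- sqrt(mean((v[ok] - mu)^2))
  if (sd_pop == 0)
    stop("normalization undefined for a constant map", call. = FALSE)
  map$raster$values <- (v - mu) / sd_pop
  map$normalized <- TRUE
  map
}

#' Combine normalized connectivity maps across species
#'
#' Cellwise unweighted mean of aligned, normalized maps: the multi-species
#' connectivity surface.
#'
#' @param maps List of normalized `connectivity_map` objects.
#' @param species Label for the combined map.
#' @return A `connectivity_map`.
#' @export
combine_species <- function(maps, species = "combined") {
  stopifnot(length(maps) >= 1L)
  for (m in maps) {
    stopifnot(inherits(m, "connectivity_map"))
    if (!isTRUE(m$normalized))
      stop("all maps must be normalized before combination", call. = FALSE)
  }
  f <- maps[[1]]$raster
  acc <- matrix(0, nrow(f$values), ncol(f$values))
  for (m in maps) {
    check_same_frame(f, m$raster, "connectivity maps")
    acc <- acc + m$raster$values
  }
  connectivity_map(grid_raster(acc / length(maps), f$origin, f$cell_size,
                               f$crs),
                   species = species, scenario = maps[[1]]$scenario,
                   normalized = TRUE)
}

#' Scenario difference map
#'
#' Cellwise `future - current`; negative cells lose connectivity under the
#' future scenario.
#'
#' @param future,current `connectivity_map` objects on the same frame and
#'   in the same normalization state.
#' @return A `grid_raster` of differences.
#' @export
delta_map <- function(future, current) {
  stopifnot(inherits(future, "connectivity_map"),
            inherits(current, "connectivity_map"))
  if (!identical(isTRUE(future$normalized), isTRUE(current$normalized)))
    stop("maps differ in normalization state", call. = FALSE)
  check_same_frame(future$raster, current$raster, "connectivity maps")
  f <- future$raster
  grid_raster(f$values - current$raster$values, f$origin, f$cell_size, f$crs)
}
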