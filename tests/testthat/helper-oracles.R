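# Brute-force oracles and small fixture builders, independent of the
# package's own algorithms.

# Pairwise-concordance AUC: count presence/absence pairs, ties = 1/2.
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Exhaustive DFS over simple paths on an 8-connected grid with the
# cost-distance move rule, with cost-bound pruning (exact).
bf_cost_distance <- function(resistance, src_cells, tgt_cells) {
  v <- resistance$values
  nr <- nrow(v); nc <- ncol(v); s <- resistance$cell_size
  nbrs <- function(cell) {
    r <- ((cell - 1) %% nr) + 1; c <- ((cell - 1) %/% nr) + 1
    out <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      cell2 <- (c2 - 1) * nr + r2
      if (is.na(v[cell2])) next
      w <- s * (v[cell] + v[cell2]) / 2 * if (dr != 0 && dc != 0) sqrt(2) else 1
      out[[length(out) + 1]] <- c(cell2, w)
    }
    out
  }
  best <- Inf
  visited <- logical(nr * nc)
  dfs <- function(cell, cost) {
    if (cost >= best) return()
    if (cell %in% tgt_cells) { best <<- cost; return() }
    visited[cell] <<- TRUE
    for (nb in nbrs(cell)) {
      if (!visited[nb[1]]) dfs(nb[1], cost + nb[2])
    }
    visited[cell] <<- FALSE
  }
  for (sc in src_cells) if (!is.na(v[sc])) dfs(sc, 0)
  best
}

# Recursive flood fill (8-connectivity) component count on a logical matrix.
bf_component_count <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  count <- 0
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    count <- count + 1
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- cur[1] + dr; c <- cur[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  count
}

# Brute-force interaction flux: double loop over all patch pairs with
# p_ij = exp(-alpha d_ij) on retained edges.
bf_interaction_flux <- function(capacities, dist_mat, alpha, d_max) {
  n <- length(capacities)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- dist_mat[i, j]
    if (is.finite(d) && d <= d_max)
      out[i] <- out[i] + capacities[i] * capacities[j] * exp(-alpha * d)
  }
  out
}

# Assemble a landscape_graph object directly from capacities + distances
# (for metric-level tests that do not need a raster).
synthetic_graph <- function(capacities, dist_mat, dispersal_dist = 1000) {
  n <- length(capacities)
  patches <- lapply(seq_len(n), function(i)
    list(id = i, cells = i, area = 1, capacity = capacities[i]))
  edges <- data.frame(i = integer(0), j = integer(0), cost = numeric(0))
  if (n > 1) {
    idx <- which(upper.tri(dist_mat), arr.ind = TRUE)
    cost <- dist_mat[idx]
    keep <- is.finite(cost) & cost <= dispersal_dist
    edges <- data.frame(i = idx[keep, 1], j = idx[keep, 2], cost = cost[keep])
  }
  structure(list(patches = patches, edges = edges, threshold = 0.5,
                 alpha = -log(0.05) / dispersal_dist,
                 dispersal_dist = dispersal_dist,
                 resistance = NULL, frame = NULL, no_graph = n == 0),
            class = "landscape_graph")
}

# Empirical semivariance of a matrix field at a horizontal lag.
semivariance <- function(field, lag) {
  d <- field[, seq_len(ncol(field) - lag)] - field[, (lag + 1):ncol(field)]
  mean(d^2) / 2
}

# Tiny flat raster helper.
flat_raster <- function(value, nr, nc, cell_size = 50) {
  grid_raster(matrix(value, nr, nc), cell_size = cell_size)
}
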