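#' Patch geometry
#'
#' A habitat element (forest patch, pond, grassland...) with an area and a
#' perimeter, either as explicit polygon rings or as a set of raster cells.
#' Only area and perimeter enter the surface-compactness index; rings (or
#' cells) are additionally used when rasterizing.
#'
#' @param rings A list of closed rings (n x 2 matrices of x, y vertices);
#'   the first ring is the exterior boundary, any further rings are holes.
#'   A single matrix is accepted as shorthand for one exterior ring.
#' @param area,perimeter Optional explicit geometry (m^2, m); computed from
#'   `rings` when those are given.
#' @return An object of class `patch_geometry`.
#' @examples
#' sq <- patch_geometry(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))
#' compactness(sq)  # pi/4 for the unit square
#' @export
patch_geometry <- function(rings = NULL, area = NULL, perimeter = NULL) {
  cells <- NULL
  if (!is.null(rings)) {
    if (is.matrix(rings)) rings <- list(rings)
    rings <- lapply(rings, close_ring)
    areas <- vapply(rings, ring_area, numeric(1))
    perims <- vapply(rings, ring_perimeter, numeric(1))
    area <- areas[1] - sum(areas[-1])
    perimeter <- sum(perims)
  }
  if (is.null(area) || is.null(perimeter))
    stop("supply `rings` or both `area` and `perimeter`", call. = FALSE)
  if (!is.finite(area) || area <= 0)
    stop("invalid geometry: area must be positive", call. = FALSE)
  if (!is.finite(perimeter) || perimeter <= 0)
    stop("invalid geometry: perimeter must be positive", call. = FALSE)
  structure(list(rings = rings, cells = cells,
                 area = area, perimeter = perimeter),
            class = "patch_geometry")
}

#' Patch geometry from raster cells
#'
#' Builds a `patch_geometry` for a set of grid cells (area = cell count x
#' cell area; perimeter = total length of exposed cell edges). Cell
#' membership is kept so the patch can be rasterized exactly.
#'
#' @param cells Linear (column-major) cell indices into `frame`.
#' @param frame The `grid_raster` frame the cells live on.
#' @export
patch_from_cells <- function(cells, frame) {
  stopifnot_raster(frame)
  cells <- unique(as.integer(cells))
  if (!length(cells)) stop("empty cell set", call. = FALSE)
  nr <- nrow(frame$values); nc <- ncol(frame$values)
  m <- matrix(FALSE, nr, nc)
  m[cells] <- TRUE
  # exposed edges: 4 per cell minus shared cardinal-neighbour edges
  shared <- 0L
  shared <- shared + sum(m[-nr, , drop = FALSE] & m[-1, , drop = FALSE])
  shared <- shared + sum(m[, -nc, drop = FALSE] & m[, -1, drop = FALSE])
  s <- frame$cell_size
  p <- patch_geometry(area = length(cells) * s^2,
                      perimeter = (4 * length(cells) - 2 * shared) * s)
  p$cells <- cells
  p$frame <- frame[c("origin", "cell_size")]
  p$frame_dim <- c(nr, nc)
  p
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2 || nrow(ring) < 3)
    stop("a ring needs >= 3 (x, y) vertices", call. = FALSE)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

ring_perimeter <- function(ring) {
  sum(sqrt(diff(ring[, 1])^2 + diff(ring[, 2])^2))
}

#' Compactness of a patch
#'
#' `4 * pi * area / perimeter^2`: 1 for a disc (isoperimetric equality) and
#' smaller for every other shape. Scale-invariant. The broader the core of a
#' patch, the closer to 1.
#'
#' @param patch A `patch_geometry`.
#' @return A number in (0, 1].
#' @export
compactness <- function(patch) {
  if (!inherits(patch, "patch_geometry"))
    stop("`patch` must be a patch_geometry", call. = FALSE)
  4 * pi * patch$area / patch$perimeter^2
}

#' Surface-compactness (SC) index
#'
#' Product of compactness and area, so that both the shape and the extent of
#' a habitat element raise its score. A disc of area A scores exactly A.
#'
#' @inheritParams compactness
#' @return A non-negative number (m^2 units).
#' @export
sc_index <- function(patch) {
  compactness(patch) * patch$area
}

# Even-odd ray-casting point-in-polygon, vectorized over points.
# Half-open boundary behaviour follows the classic crossing rule.
points_in_ring <- function(px, py, ring) {
  inside <- logical(length(px))
  n <- nrow(ring)
  j <- n - 1L  # ring is closed; last vertex repeats the first
  for (i in seq_len(n - 1L)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

points_in_patch <- function(px, py, patch) {
  inside <- logical(length(px))
  for (ring in patch$rings) inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

#' Rasterize the SC index of a patch set
#'
#' Each cell carries the SC index of the patch overlapping its centre
#' (cell-center-in-polygon rule), 0 where no patch overlaps. When several
#' patches overlap a cell centre the later patch in `patches` wins.
#'
#' @param patches List of `patch_geometry` objects (polygon- or cell-based).
#' @param frame Target `grid_raster` frame.
#' @return A `grid_raster` of SC values.
#' @export
rasterize_sc <- function(patches, frame) {
  stopifnot_raster(frame)
  out <- matrix(0, nrow(frame$values), ncol(frame$values))
  cc <- NULL
  for (p in patches) {
    sc <- sc_index(p)
    if (!is.null(p$cells)) {
      if (!is.null(p$frame_dim) && !all(p$frame_dim == dim(frame)))
        stop("cell-based patch is not on the target frame", call. = FALSE)
      out[p$cells] <- sc
    } else {
      if (is.null(cc)) cc <- cell_centers(frame)
      hit <- points_in_patch(cc$x, cc$y, p)
      out[cc$cell[hit]] <- sc
    }
  }
  grid_raster(out, origin = frame$origin, cell_size = frame$cell_size,
              crs = frame$crs)
}

#' Distance to the nearest element
#'
#' Planar Euclidean distance (metres) from every cell centre to the nearest
#' element of a point set (ponds, springs, water courses vertices...).
#'
#' @param elements A data.frame / matrix with `x`, `y` columns (>= 1 row).
#' @param frame Target `grid_raster` frame.
#' @return A `grid_raster` of distances.
#' @export
distance_to_nearest <- function(elements, frame) {
  stopifnot_raster(frame)
  el <- as.data.frame(elements)
  if (!nrow(el)) stop("empty element set", call. = FALSE)
  cc <- cell_centers(frame)
  best <- rep(Inf, nrow(cc))
  # chunk over elements to bound the ncell x nelement temporary
  chunk <- max(1L, floor(2e6 / nrow(cc)))
  for (start in seq(1L, nrow(el), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(el))
    d2 <- outer(cc$x, el$x[idx], "-")^2 + outer(cc$y, el$y[idx], "-")^2
    best <- pmin(best, sqrt(do.call(pmin, as.data.frame(d2))))
  }
  grid_raster(matrix(best, nrow(frame$values), ncol(frame$values)),
              origin = frame$origin, cell_size = frame$cell_size,
              crs = frame$crs)
}
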