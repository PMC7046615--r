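#' Georeferenced grid raster
#'
#' Minimal in-memory raster: a numeric matrix in a planar (projected, metres)
#' frame. Row 1 is the northernmost row (north-up); `NA` marks nodata.
#' Cell `(r, c)` covers the half-open square
#' `[x0 + (c-1)s, x0 + cs) x (y0 - rs, y0 - (r-1)s]`
#' where `(x0, y0)` is the top-left corner and `s` the cell size.
#'
#' Linear cell indices used throughout the package are R's native
#' column-major indices into the value matrix.
#'
#' @param values Numeric matrix (row 1 = north).
#' @param origin Numeric length-2, `(x, y)` of the top-left corner.
#' @param cell_size Cell edge length in metres (single positive number).
#' @param crs Opaque CRS tag; purely informative.
#' @return An object of class `grid_raster`.
#' @examples
#' r <- grid_raster(matrix(1:6, 2, 3), origin = c(0, 100), cell_size = 50)
#' dim(r)
#' @export
grid_raster <- function(values, origin = c(0, 0), cell_size = 1,
                        crs = "local-metric") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  if (length(origin) != 2L || anyNA(origin))
    stop("`origin` must be (x, y) of the top-left corner", call. = FALSE)
  if (any(dim(values) <= 0))
    stop("raster must have positive dimensions", call. = FALSE)
  structure(
    list(values = values, origin = as.numeric(origin),
         cell_size = as.numeric(cell_size), crs = as.character(crs)[1]),
    class = "grid_raster"
  )
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<grid_raster> %d x %d cells of %g m, origin (%g, %g), crs '%s'\n",
    nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2], x$crs))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(v))))
  invisible(x)
}

is_grid_raster <- function(x) inherits(x, "grid_raster")

stopifnot_raster <- function(x, arg = deparse(substitute(x))) {
  if (!is_grid_raster(x))
    stop(sprintf("`%s` must be a grid_raster", arg), call. = FALSE)
  invisible(x)
}

#' Test whether two rasters share the same frame
#'
#' Frames match when dimensions, origin and cell size agree (within `tol`).
#'
#' @param a,b `grid_raster` objects.
#' @param tol Numeric tolerance on origin and cell size.
#' @export
same_frame <- function(a, b, tol = 1e-9) {
  stopifnot_raster(a); stopifnot_raster(b)
  all(dim(a) == dim(b)) &&
    all(abs(a$origin - b$origin) <= tol) &&
    abs(a$cell_size - b$cell_size) <= tol
}

check_same_frame <- function(a, b, what = "rasters") {
  if (!same_frame(a, b))
    stop(sprintf("%s are not on the same grid frame", what), call. = FALSE)
  invisible(TRUE)
}

#' Cell centre coordinates
#'
#' @param frame A `grid_raster`.
#' @param cells Linear (column-major) cell indices; default all cells.
#' @return data.frame with `cell`, `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(frame, cells = NULL) {
  stopifnot_raster(frame)
  nr <- nrow(frame$values)
  if (is.null(cells)) cells <- seq_len(length(frame$values))
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  s <- frame$cell_size
  data.frame(cell = cells, row = r, col = c,
             x = frame$origin[1] + (c - 0.5) * s,
             y = frame$origin[2] - (r - 0.5) * s)
}

#' Map planar coordinates to cells
#'
#' Uses the half-open cell convention: a point on the western or northern
#' edge of a cell belongs to that cell.
#'
#' @inheritParams cell_centers
#' @param x,y Coordinate vectors (metres).
#' @return data.frame with `row`, `col`, `cell` (`NA` outside the frame).
#' @export
xy_to_cell <- function(frame, x, y) {
  stopifnot_raster(frame)
  s <- frame$cell_size
  nr <- nrow(frame$values); nc <- ncol(frame$values)
  col <- floor((x - frame$origin[1]) / s) + 1
  row <- floor((frame$origin[2] - y) / s) + 1
  # top/left edges: y == y0 maps into row 1, handled; y == y0 - nr*s is outside
  row[frame$origin[2] - y == 0] <- 1L
  bad <- row < 1 | row > nr | col < 1 | col > nc
  row[bad] <- NA; col[bad] <- NA
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((col - 1L) * nr + row))
}

#' Extract raster values at point locations
#'
#' @inheritParams xy_to_cell
#' @return Numeric vector (`NA` outside the frame or at nodata cells).
#' @export
raster_extract <- function(frame, x, y) {
  rc <- xy_to_cell(frame, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$cell)
  out[ok] <- frame$values[rc$cell[ok]]
  out
}

#' Disaggregate a coarse raster onto a fine grid
#'
#' Block replication (nearest neighbour): every fine cell takes the value of
#' the coarse cell containing it, so the coarse values are kept unchanged at
#' higher resolution. Used to bring coarse climate suitability onto the fine
#' land-cover grid before multiplying the two.
#'
#' @param coarse A `grid_raster`.
#' @param fine_frame Optional target `grid_raster` frame. Its cell size must
#'   divide the coarse cell size exactly and origins must coincide.
#' @param factor Integer replication factor; used when `fine_frame` is NULL.
#' @return A `grid_raster` on the fine frame.
#' @export
disaggregate <- function(coarse, fine_frame = NULL, factor = NULL) {
  stopifnot_raster(coarse)
  if (is.null(fine_frame) && is.null(factor))
    stop("supply `fine_frame` or `factor`", call. = FALSE)
  if (!is.null(fine_frame)) {
    stopifnot_raster(fine_frame)
    f <- coarse$cell_size / fine_frame$cell_size
    if (abs(f - round(f)) > 1e-9)
      stop("fine cell size must divide coarse cell size exactly",
           call. = FALSE)
    f <- as.integer(round(f))
    if (any(abs(coarse$origin - fine_frame$origin) > 1e-9))
      stop("frames are not aligned: origins differ", call. = FALSE)
    if (!all(dim(fine_frame) == dim(coarse) * f))
      stop("frames are not aligned: dimensions do not match factor",
           call. = FALSE)
  } else {
    f <- as.integer(factor)
    if (f < 1) stop("`factor` must be >= 1", call. = FALSE)
  }
  v <- coarse$values
  fine_v <- v[rep(seq_len(nrow(v)), each = f), rep(seq_len(ncol(v)), each = f),
              drop = FALSE]
  grid_raster(fine_v, origin = coarse$origin,
              cell_size = coarse$cell_size / f, crs = coarse$crs)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize/`
#' `NODATA_value` header, then rows north to south). The CRS tag is stored in
#' a `.prj` sidecar file. Round-trips preserve values, frame and nodata.
#'
#' @param r A `grid_raster`.
#' @param path Output path (conventionally `.asc`).
#' @return `write_asc` returns `path` invisibly; `read_asc` a `grid_raster`.
#' @export
write_asc <- function(r, path) {
  stopifnot_raster(r)
  v <- r$values
  nr <- nrow(v); nc <- ncol(v); s <- r$cell_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", r$origin[1]),
    sprintf("yllcorner %.10f", r$origin[2] - nr * s),
    sprintf("cellsize %.10f", s),
    "NODATA_value -9999")
  vv <- v
  vv[is.na(vv)] <- -9999
  rows <- apply(vv, 1L, function(row) paste(formatC(row, format = "g",
                                                    digits = 17),
                                            collapse = " "))
  writeLines(c(hdr, rows), path)
  writeLines(r$crs, paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields", call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)),
         call. = FALSE)
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  v[v == nodata] <- NA
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  crs <- if (file.exists(prj)) readLines(prj, n = 1L) else "local-metric"
  s <- hdr$cellsize
  grid_raster(v, origin = c(hdr$xllcorner, hdr$yllcorner + nr * s),
              cell_size = s, crs = crs)
}

# Pairs of 8-neighbour cells as column-major linear indices.
# Returns list(from, to, diag) covering each undirected pair once.
neighbor_pairs <- function(nr, nc, diagonal = TRUE) {
  id <- matrix(seq_len(nr * nc), nr, nc)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (diagonal) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- to <- integer(0); dg <- logical(0)
  for (o in offs) {
    dr <- o[1]; dc <- o[2]
    rows <- seq_len(nr)[seq_len(nr) + dr >= 1 & seq_len(nr) + dr <= nr]
    cols <- seq_len(nc)[seq_len(nc) + dc >= 1 & seq_len(nc) + dc <= nc]
    if (!length(rows) || !length(cols)) next
    f <- id[rows, cols, drop = FALSE]
    t <- id[rows + dr, cols + dc, drop = FALSE]
    from <- c(from, as.vector(f)); to <- c(to, as.vector(t))
    dg <- c(dg, rep(dr != 0L & dc != 0L, length(f)))
  }
  list(from = from, to = to, diag = dg)
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
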