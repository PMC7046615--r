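#' Read / write occurrence CSVs
#'
#' Occurrences travel as plain CSV with columns `species`, `x`, `y`
#' (projected metres). Reading validates every row and names the first
#' malformed one; coordinates round-trip at full precision.
#'
#' @param path File path.
#' @param occ data.frame with `species`, `x`, `y`.
#' @return `read_occurrences` returns the data.frame; `write_occurrences`
#'   the path, invisibly.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "x", "y")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns species, x, y", call. = FALSE)
  x <- suppressWarnings(as.numeric(df$x))
  y <- suppressWarnings(as.numeric(df$y))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad))
    stop(sprintf("malformed occurrence row %d: non-numeric coordinates",
                 bad[1]), call. = FALSE)
  data.frame(species = df$species, x = x, y = y, stringsAsFactors = FALSE)
}

#' @rdname read_occurrences
#' @export
write_occurrences <- function(occ, path) {
  df <- as.data.frame(occ)[, c("species", "x", "y")]
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write points or patches as GeoJSON
#'
#' Points become a FeatureCollection of Point features (extra columns as
#' properties). Cell-based patches become MultiPolygon features made of
#' their cell squares; ring-based patches become Polygon features.
#'
#' @param x data.frame with `x`, `y` (points) or a list of `patch_geometry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  if (is.data.frame(x)) {
    props <- x[, setdiff(names(x), c("x", "y")), drop = FALSE]
    feats <- lapply(seq_len(nrow(x)), function(i) {
      pr <- as.list(props[i, , drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(x$x[i], x$y[i])),
           properties = if (length(pr)) pr else stats::setNames(list(), character(0)))
    })
  } else if (is.list(x) && all(vapply(x, inherits, logical(1),
                                      "patch_geometry"))) {
    feats <- lapply(seq_along(x), function(i) {
      p <- x[[i]]
      geom <- if (!is.null(p$rings)) {
        list(type = "Polygon",
             coordinates = lapply(p$rings, function(r)
               lapply(seq_len(nrow(r)), function(k) r[k, ])))
      } else {
        s <- p$frame$cell_size; x0 <- p$frame$origin[1]; y0 <- p$frame$origin[2]
        nr <- p$frame_dim[1]
        polys <- lapply(p$cells, function(cl) {
          r <- ((cl - 1L) %% nr) + 1L
          c <- ((cl - 1L) %/% nr) + 1L
          xs <- x0 + (c - 1) * s; ys <- y0 - r * s
          list(list(c(xs, ys), c(xs + s, ys), c(xs + s, ys + s),
                    c(xs, ys + s), c(xs, ys)))
        })
        list(type = "MultiPolygon", coordinates = polys)
      }
      list(type = "Feature", geometry = geom,
           properties = list(id = i, area = p$area, perimeter = p$perimeter))
    })
  } else stop("cannot write this object as GeoJSON", call. = FALSE)
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read GeoJSON point features
#'
#' @param path GeoJSON file with Point features.
#' @return data.frame with `x`, `y` and any scalar properties.
#' @export
read_geojson_points <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  pts <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("not a Point feature collection", call. = FALSE)
    co <- unlist(f$geometry$coordinates)
    row <- list(x = co[1], y = co[2])
    for (nm in names(f$properties)) row[[nm]] <- f$properties[[nm]]
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  do.call(rbind, pts)
}
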