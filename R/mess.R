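#' Reference envelope for similarity analysis
#'
#' Per-variable sorted reference values (typically covariate values at the
#' calibration occurrences), the envelope against which projection
#' conditions are compared.
#'
#' @param ref data.frame / matrix of reference values (>= 2 rows).
#' @return An object of class `reference_envelope`.
#' @export
reference_envelope <- function(ref) {
  ref <- as.data.frame(ref)
  if (nrow(ref) < 2L)
    stop("need >= 2 reference points per variable", call. = FALSE)
  vals <- lapply(ref, function(v) sort(v[!is.na(v)]))
  structure(list(values = vals,
                 min = vapply(vals, min, numeric(1)),
                 max = vapply(vals, max, numeric(1))),
            class = "reference_envelope")
}

#' Single-variable environmental similarity
#'
#' With `f` the percentage of reference values strictly below `value`:
#' `100 (value - min) / (max - min)` when `f = 0`;
#' `100 (max - value) / (max - min)` when `f = 100`;
#' `2 f` when `f <= 50`; else `2 (100 - f)`. Piecewise linear and
#' continuous, 100 at the reference median, negative outside the reference
#' range.
#'
#' @param value Numeric vector of projection values.
#' @param ref Numeric vector of reference values (non-constant).
#' @return Similarity values (same length as `value`).
#' @export
mess_variable <- function(value, ref) {
  ref <- sort(ref[!is.na(ref)])
  if (!length(ref)) stop("empty reference set", call. = FALSE)
  mn <- ref[1]; mx <- ref[length(ref)]
  if (mx == mn)
    stop("similarity undefined for a constant reference", call. = FALSE)
  f <- 100 * findInterval(value, ref, left.open = TRUE) / length(ref)
  out <- ifelse(f == 0, 100 * (value - mn) / (mx - mn),
         ifelse(f == 100, 100 * (mx - value) / (mx - mn),
         ifelse(f <= 50, 2 * f, 2 * (100 - f))))
  out[is.na(value)] <- NA
  out
}

#' Multivariate environmental similarity surface (MESS)
#'
#' Per-cell minimum over variables of the single-variable similarity to the
#' calibration envelope. Negative cells flag extrapolation: projecting the
#' model there means leaving the environments it was calibrated on, and the
#' more negative, the more novel the environment.
#'
#' @param rasters Named list of aligned `grid_raster` projection layers.
#' @param envelope A `reference_envelope` whose variables match `rasters`.
#' @return A `grid_raster` of similarity values.
#' @export
mess_surface <- function(rasters, envelope) {
  stopifnot(inherits(envelope, "reference_envelope"))
  vars <- names(envelope$values)
  missing <- setdiff(vars, names(rasters))
  if (length(missing))
    stop("projection rasters missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  frame <- rasters[[vars[1]]]
  out <- NULL
  for (v in vars) {
    check_same_frame(frame, rasters[[v]], "projection rasters")
    m <- mess_variable(as.vector(rasters[[v]]$values), envelope$values[[v]])
    out <- if (is.null(out)) m else pmin(out, m)
  }
  grid_raster(matrix(out, nrow(frame$values)), frame$origin,
              frame$cell_size, frame$crs)
}
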