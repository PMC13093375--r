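#' Create an analysis grid
#'
#' The grid is the shared geometry for every raster layer, mask and
#' assemblage in an analysis. Cell (1, 1) is the upper-left cell; cell
#' centers are at `origin_x + (col - 0.5) * cell_size` and
#' `origin_y - (row - 0.5) * cell_size`, so y decreases with row. All
#' layers in one analysis must share a bitwise-identical grid; the study
#' design uses 4.5 x 4.5 km sampling units.
#'
#' @param origin_x,origin_y Coordinate of the grid's upper-left corner
#'   (km for the synthetic Cartesian CRS, or the units of a projected
#'   metric CRS).
#' @param cell_size Cell edge length in the same units. Must be positive.
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param nodata Sentinel value used for missing cells on disk; in memory
#'   missing cells are `NA`.
#' @param crs_tag Free-text CRS label; `"synthetic-cartesian"` marks the
#'   simulated km grid. Distance-based operations refuse geographic
#'   (degree) grids because the study's 4.5 km cells and 100 km buffers
#'   are metric.
#' @return An object of class `pr_grid`.
#' @export
pr_grid <- function(origin_x = 0, origin_y = 0, cell_size = 4.5,
                    n_rows = 100, n_cols = 100, nodata = -9999,
                    crs_tag = "synthetic-cartesian") {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be positive integers")
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size), n_rows = n_rows, n_cols = n_cols,
         nodata = as.numeric(nodata), crs_tag = as.character(crs_tag)),
    class = "pr_grid")
}

#' Test two grids for identical geometry
#'
#' @param a,b `pr_grid` objects.
#' @return `TRUE` iff origin, cell size and dimensions are all equal.
#' @export
grid_equal <- function(a, b) {
  stopifnot(inherits(a, "pr_grid"), inherits(b, "pr_grid"))
  isTRUE(a$origin_x == b$origin_x && a$origin_y == b$origin_y &&
         a$cell_size == b$cell_size && a$n_rows == b$n_rows &&
         a$n_cols == b$n_cols)
}

stop_if_grid_mismatch <- function(a, b, what = "layer") {
  if (!grid_equal(a, b))
    stop("grid geometry of ", what,
         " does not match the reference grid of this analysis")
  invisible(TRUE)
}

stop_if_geographic <- function(grid, op = "this operation") {
  if (grepl("degree|geographic|epsg:4326|wgs84", tolower(grid$crs_tag)))
    stop(op, " requires a projected metric CRS; got '", grid$crs_tag, "'")
  invisible(TRUE)
}

#' Cell-center coordinates
#'
#' @param grid A `pr_grid`.
#' @return A data frame with one row per cell in row-major order
#'   (row 1 first), columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(grid) {
  stopifnot(inherits(grid, "pr_grid"))
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(row = row, col = col,
             x = grid$origin_x + (col - 0.5) * grid$cell_size,
             y = grid$origin_y - (row - 0.5) * grid$cell_size)
}

#' Create a raster layer on a grid
#'
#' @param grid A `pr_grid`.
#' @param values Numeric matrix of dimension `n_rows x n_cols`; `NA`
#'   marks nodata cells, which are excluded from all statistics.
#' @param variable Variable label (e.g. `"BIO1"`, `"BIO12"`,
#'   `"tree_density"`, `"suitability"`).
#' @return An object of class `pr_raster`.
#' @export
pr_raster <- function(grid, values, variable = "value") {
  stopifnot(inherits(grid, "pr_grid"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("values matrix (", nrow(values), "x", ncol(values),
         ") does not match grid (", grid$n_rows, "x", grid$n_cols, ")")
  structure(list(grid = grid, values = values,
                 variable = as.character(variable)),
            class = "pr_raster")
}

#' Create a binary mask layer on a grid
#'
#' @param grid A `pr_grid`.
#' @param values Matrix with entries in `{0, 1, NA}`.
#' @param role One of `"range"`, `"refugium"`, `"protected_area"`,
#'   `"forest_cover"`, `"study_area"`.
#' @return An object of class `pr_mask` (also a `pr_raster`).
#' @export
pr_mask <- function(grid, values, role = "range") {
  role <- match.arg(role, c("range", "refugium", "protected_area",
                            "forest_cover", "study_area"))
  v <- values[!is.na(values)]
  if (length(v) && !all(v %in% c(0, 1)))
    stop("mask values must be 0, 1 or NA")
  r <- pr_raster(grid, values, variable = role)
  r$role <- role
  class(r) <- c("pr_mask", "pr_raster")
  r
}

#' @export
print.pr_grid <- function(x, ...) {
  cat(sprintf("<pr_grid %dx%d, cell %g, origin (%g, %g), crs '%s'>\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y,
              x$crs_tag))
  invisible(x)
}

#' @export
print.pr_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<pr_raster '%s' %dx%d, %d nodata, range [%g, %g]>\n",
              x$variable, x$grid$n_rows, x$grid$n_cols,
              sum(is.na(x$values)),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# Summary statistic over the non-nodata cells of a layer.
layer_mean <- function(layer) mean(layer$values, na.rm = TRUE)

# Jaccard similarity of two binary masks on one grid (NA cells ignored).
#' Jaccard similarity between two masks
#'
#' Intersection over union of the 1-cells; used to compare delineated
#' refugia with a reference (e.g. planted core) region.
#'
#' @param a,b `pr_mask` layers on the same grid.
#' @return Scalar in \[0, 1\]; `NaN` when both masks are empty.
#' @export
mask_jaccard <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "mask")
  av <- !is.na(a$values) & a$values == 1
  bv <- !is.na(b$values) & b$values == 1
  inter <- sum(av & bv); uni <- sum(av | bv)
  if (uni == 0) return(NaN)
  inter / uni
}
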