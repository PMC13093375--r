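#' Read a single-band raster from an ESRI ASCII grid file
#'
#' The package's raster interchange format is the plain-text ESRI ASCII
#' grid (`.asc`): a six-line header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by the value matrix,
#' top row first. The format is human-readable, diff-able, and read by
#' GDAL/QGIS. GeoTIFF input is refused with an informative error.
#'
#' @param path Path to a `.asc` file.
#' @param variable Variable label for the returned layer; defaults to the
#'   file name without extension.
#' @param crs_tag CRS label to attach (the ASCII grid header carries no
#'   CRS); defaults to `"synthetic-cartesian"`.
#' @param reference_grid Optional `pr_grid`; if supplied, the file's
#'   geometry must match it exactly (strict mode).
#' @return A `pr_raster` with nodata cells as `NA`.
#' @export
read_raster <- function(path, variable = NULL,
                        crs_tag = "synthetic-cartesian",
                        reference_grid = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("GeoTIFF is not supported by this build; convert to the ",
         "documented ASCII grid dialect (.asc), e.g. with ",
         "'gdal_translate -of AAIGrid'")
  lines <- readLines(path)
  if (length(lines) < 7) stop("not an ASCII grid (too short): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed header line ", i, " in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != n_rows * n_cols)
    stop("expected ", n_rows * n_cols, " values, found ", length(vals),
         " in ", path)
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  grid <- pr_grid(origin_x = hdr$xllcorner,
                  origin_y = hdr$yllcorner + n_rows * hdr$cellsize,
                  cell_size = hdr$cellsize, n_rows = n_rows,
                  n_cols = n_cols, nodata = hdr$nodata_value,
                  crs_tag = crs_tag)
  if (!is.null(reference_grid))
    stop_if_grid_mismatch(reference_grid, grid, paste0("file ", path))
  if (is.null(variable))
    variable <- sub("\\.[^.]*$", "", basename(path))
  pr_raster(grid, m, variable = variable)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' Round-trips losslessly through [read_raster()]: values are written
#' with full precision (`%.17g`) and `NA` cells as the grid's nodata
#' sentinel.
#'
#' @param layer A `pr_raster`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "pr_raster"))
  g <- layer$grid
  m <- layer$values
  m[is.na(m)] <- g$nodata
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.17g", g$origin_x),
           sprintf("yllcorner %.17g", g$origin_y - g$n_rows * g$cell_size),
           sprintf("cellsize %.17g", g$cell_size),
           sprintf("NODATA_value %.17g", g$nodata))
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read species occurrence records
#'
#' Expects a CSV with mandatory columns `species`, `x`, `y`. Exact
#' duplicate coordinates within a species are collapsed to one record; a
#' species is flagged modelable only when it retains more than 10 unique
#' records (a standard reliability floor for niche models).
#'
#' @param path CSV path.
#' @param min_records Unique-record count a species must exceed to be
#'   modelable (default 10).
#' @return Named list of `pr_occurrences` objects, one per species, each
#'   with fields `species`, `points` (two-column matrix), `n_unique`,
#'   `modelable`.
#' @export
read_occurrences <- function(path, min_records = 10) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("species", "x", "y"), names(df))
  if (length(miss))
    stop("occurrence CSV missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$x) || !is.numeric(df$y))
    stop("occurrence coordinates must be numeric")
  occurrence_sets(df, min_records = min_records)
}

#' Build occurrence sets from a data frame
#'
#' @param df Data frame with columns `species`, `x`, `y`.
#' @param min_records See [read_occurrences()].
#' @return Named list of `pr_occurrences`.
#' @export
occurrence_sets <- function(df, min_records = 10) {
  out <- lapply(split(df, df$species), function(d) {
    pts <- unique(as.matrix(d[, c("x", "y")]))
    dimnames(pts) <- list(NULL, c("x", "y"))
    structure(list(species = d$species[1], points = pts,
                   n_unique = nrow(pts),
                   modelable = nrow(pts) > min_records),
              class = "pr_occurrences")
  })
  out[order(names(out))]
}

#' Read a rooted phylogeny with branch lengths
#'
#' Thin validating wrapper around [ape::read.tree()]: the tree must be
#' rooted, carry branch lengths on every edge, and have unique tip
#' labels. Zero-length branches are tolerated but reported.
#'
#' @param path Newick file path.
#' @return An `ape::phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  if (is.null(tr$edge.length) || anyNA(tr$edge.length) ||
      length(tr$edge.length) != nrow(tr$edge))
    stop("tree must have a branch length on every edge")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip names in tree")
  nz <- sum(tr$edge.length == 0)
  if (nz > 0)
    message("tree accepted with ", nz, " zero-length branch(es)")
  tr
}

#' Read polygons from a GeoJSON file
#'
#' Supports `FeatureCollection`, `Feature`, `Polygon`, `MultiPolygon` and
#' `GeometryCollection`. Coordinates must already be in the analysis
#' grid's CRS (no reprojection is performed).
#'
#' @param path GeoJSON file path.
#' @return List of polygons; each polygon is a list of rings, each ring a
#'   two-column coordinate matrix (outer ring first; interior rings are
#'   holes under the even-odd rule).
#' @export
read_geojson_polygons <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- list()
  add_geom <- function(geom) {
    if (is.null(geom)) return(invisible())
    type <- geom$type
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (identical(type, "Polygon")) {
      polys[[length(polys) + 1L]] <<- lapply(geom$coordinates, ring_mat)
    } else if (identical(type, "MultiPolygon")) {
      for (poly in geom$coordinates)
        polys[[length(polys) + 1L]] <<- lapply(poly, ring_mat)
    } else if (identical(type, "GeometryCollection")) {
      for (g in geom$geometries) add_geom(g)
    } else {
      stop("unsupported GeoJSON geometry type: ", type)
    }
  }
  if (identical(gj$type, "FeatureCollection")) {
    for (f in gj$features) add_geom(f$geometry)
  } else if (identical(gj$type, "Feature")) {
    add_geom(gj$geometry)
  } else {
    add_geom(gj)
  }
  polys
}

# Even-odd point-in-polygon test for one ring; vectorized over points.
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, polygon) {
  inside <- rep(FALSE, length(px))
  for (ring in polygon)
    inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

#' Rasterize polygons to a binary mask (center-point rule)
#'
#' A cell is 1 iff its center falls inside any polygon (even-odd rule, so
#' interior rings act as holes). The center-point rule is deterministic
#' and area-unbiased at the study's 4.5 km resolution. Adding polygons
#' can only turn 0-cells into 1-cells (monotone union).
#'
#' @param polygons List of polygons as returned by
#'   [read_geojson_polygons()]; a single two-column matrix is also
#'   accepted as one ring.
#' @param grid Target `pr_grid`.
#' @param role Mask role label (see [pr_mask()]).
#' @return A `pr_mask`. An empty polygon list yields an all-zero mask
#'   with a warning.
#' @export
rasterize_mask <- function(polygons, grid, role = "range") {
  stopifnot(inherits(grid, "pr_grid"))
  if (is.matrix(polygons)) polygons <- list(list(polygons))
  vals <- matrix(0, grid$n_rows, grid$n_cols)
  if (length(polygons) == 0) {
    warning("empty polygon collection: mask is all zero")
    return(pr_mask(grid, vals, role = role))
  }
  cc <- cell_centers(grid)
  inside <- rep(FALSE, nrow(cc))
  for (poly in polygons)
    inside <- inside | points_in_polygon(cc$x, cc$y, poly)
  vals[cbind(cc$row, cc$col)] <- as.numeric(inside)
  pr_mask(grid, vals, role = role)
}
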