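#' Build the per-species persistence table
#'
#' Counts, for every cell and species, the number of paleo slices (out
#' of T) in which the species' thresholded hindcast is suitable. Nodata
#' cells (nodata in any slice for a species) stay nodata for that
#' species.
#'
#' @param binary_maps Named list (one element per species) of lists of
#'   `pr_mask` layers, one per slice; all on one grid, every species with
#'   a map for every slice.
#' @return A `pr_persistence` object: array `n_rows x n_cols x S` of
#'   slice counts plus `grid`, `T`, `species`.
#' @export
build_persistence <- function(binary_maps) {
  if (length(binary_maps) == 0) stop("no species maps supplied")
  Ts <- vapply(binary_maps, length, integer(1))
  if (length(unique(Ts)) != 1 || Ts[1] == 0)
    stop("every species must have a map for every slice")
  T <- unname(Ts[1])
  grid <- binary_maps[[1]][[1]]$grid
  species <- names(binary_maps)
  if (is.null(species)) species <- sprintf("species_%d", seq_along(binary_maps))
  counts <- array(0, dim = c(grid$n_rows, grid$n_cols, length(binary_maps)),
                  dimnames = list(NULL, NULL, species))
  for (s in seq_along(binary_maps)) {
    acc <- matrix(0, grid$n_rows, grid$n_cols)
    nas <- matrix(FALSE, grid$n_rows, grid$n_cols)
    for (m in binary_maps[[s]]) {
      stop_if_grid_mismatch(grid, m$grid, "slice mask")
      v <- m$values
      nas <- nas | is.na(v)
      v[is.na(v)] <- 0
      acc <- acc + v
    }
    acc[nas] <- NA
    counts[, , s] <- acc
  }
  structure(list(counts = counts, grid = grid, T = T, species = species),
            class = "pr_persistence")
}

#' Stack persistence into the forest-stability surface
#'
#' Sums the thresholded hindcasts over all species and all time periods:
#' `counts` is the per-cell number of suitable (species, slice) pairs and
#' `normalized = counts / (S * T)` is the 0-1 stability estimate.
#'
#' @param table A `pr_persistence`.
#' @return A `pr_stability` object with `counts` and `normalized`
#'   `pr_raster`s plus `S` and `T`.
#' @export
stack_stability <- function(table) {
  stopifnot(inherits(table, "pr_persistence"))
  S <- dim(table$counts)[3]
  counts <- apply(table$counts, c(1, 2), sum)
  structure(list(
    counts = pr_raster(table$grid, counts, "stability_count"),
    normalized = pr_raster(table$grid, counts / (S * table$T),
                           "forest_stability"),
    S = S, T = table$T),
    class = "pr_stability")
}

#' Delineate refugia from the persistence table
#'
#' A cell is refugial when at least `ceiling(p * S)` species each persist
#' (are suitable) in at least `tau` of the T slices at that cell. The
#' study's strictest class uses p = 0.95 and tau = 230 of 257 slices.
#'
#' @param table A `pr_persistence`.
#' @param p Species fraction in (0, 1].
#' @param tau Temporal cutoff in slices, `1 <= tau <= T`.
#' @return A binary `pr_mask` with role `"refugium"`.
#' @export
delineate_refugia <- function(table, p, tau) {
  stopifnot(inherits(table, "pr_persistence"))
  if (!(p > 0 && p <= 1)) stop("p must be in (0, 1]")
  if (!(tau >= 1 && tau <= table$T)) stop("tau must be in [1, T]")
  S <- dim(table$counts)[3]
  need <- ceiling(p * S)
  n_persist <- apply(table$counts >= tau, c(1, 2), sum)
  vals <- (n_persist >= need) * 1
  vals[apply(is.na(table$counts), c(1, 2), any)] <- NA
  pr_mask(table$grid, vals, role = "refugium")
}

#' Nested refugia masks for several species fractions
#'
#' @param table A `pr_persistence`.
#' @param fractions Species fractions (default the study's 0.50, 0.75,
#'   0.90, 0.95); masks are nested: stricter fractions are subsets.
#' @param tau Temporal cutoff in slices.
#' @return Named list of `pr_mask`s keyed by fraction (e.g. `"0.95"`).
#' @export
refugia_set <- function(table, fractions = c(0.5, 0.75, 0.9, 0.95),
                        tau) {
  out <- lapply(fractions, function(p) delineate_refugia(table, p, tau))
  names(out) <- format(fractions)
  out
}

#' Climate stability from a paleoclimate stack
#'
#' For each consecutive pair of slices, the pair deviation at a cell is
#' the (population) standard deviation of the two values, `|a - b| / 2`,
#' divided by the elapsed time between the slices. The per-cell deviation
#' is the mean over the T - 1 pairs; stability is its inverse, rescaled
#' to \[0, 1\] by the finite maximum. Cells with zero deviation (constant
#' series) receive stability 1. Present-day layers are excluded by
#' construction: only the paleo stack enters.
#'
#' @param stack A `pr_timestack` (fields `grid`, `ages`, `layers`).
#' @param variable Climate variable label present in every slice.
#' @return A `pr_climstab` object with `deviation` and `stability`
#'   `pr_raster`s.
#' @export
climate_stability <- function(stack, variable) {
  ages <- stack$ages
  T <- length(ages)
  if (T < 2) stop("need at least two time slices")
  dev <- matrix(0, stack$grid$n_rows, stack$grid$n_cols)
  for (i in seq_len(T - 1)) {
    a <- stack$layers[[i]][[variable]]$values
    b <- stack$layers[[i + 1]][[variable]]$values
    dev <- dev + (abs(a - b) / 2) / abs(ages[i] - ages[i + 1])
  }
  dev <- dev / (T - 1)
  inv <- 1 / dev  # Inf where deviation is 0
  mx <- max(inv[is.finite(inv)], na.rm = TRUE)
  stab <- inv / mx
  stab[dev == 0] <- 1
  structure(list(
    deviation = pr_raster(stack$grid, dev,
                          paste0(variable, "_deviation")),
    stability = pr_raster(stack$grid, stab,
                          paste0(variable, "_stability"))),
    class = "pr_climstab")
}

#' Distance-to-refugium surface
#'
#' Per-cell Euclidean distance (km) from the cell center to the nearest
#' refugium cell center; refugium cells get 0. Center-to-center distance
#' approximates edge distance at sub-cell precision on the study's
#' 4.5 km grid. Requires a metric CRS and a nonempty mask.
#'
#' @param refugium A `pr_mask` with at least one 1-cell.
#' @return A `pr_raster` labelled `"distance_to_refugium"` (km).
#' @export
distance_to_refugia <- function(refugium) {
  stopifnot(inherits(refugium, "pr_mask"))
  stop_if_geographic(refugium$grid, "distance_to_refugia")
  if (!any(refugium$values == 1, na.rm = TRUE))
    stop("refugium mask is empty")
  pr_raster(refugium$grid, mask_distance_values(refugium),
            "distance_to_refugium")
}
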