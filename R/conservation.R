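#' Fraction of a refugium that is protected
#'
#' Cell-count overlap on the shared grid: protected refugium cells
#' divided by all refugium cells.
#'
#' @param refugium,pa `pr_mask` layers on one grid; the refugium must be
#'   nonempty.
#' @return Fraction in \[0, 1\].
#' @export
overlap_fraction <- function(refugium, pa) {
  stop_if_grid_mismatch(refugium$grid, pa$grid, "protected-area mask")
  ref <- !is.na(refugium$values) & refugium$values == 1
  if (!any(ref)) stop("refugium mask is empty")
  prot <- !is.na(pa$values) & pa$values == 1
  sum(ref & prot) / sum(ref)
}

#' Mean richness per mask category
#'
#' @param richness Richness `pr_raster`.
#' @param category_masks Named list of `pr_mask`s on the same grid.
#' @return Named numeric vector of mean richness over each mask's
#'   non-nodata 1-cells; `NA` (undefined, not zero) for empty masks.
#' @export
mean_richness_by_category <- function(richness, category_masks) {
  vapply(category_masks, function(m) {
    stop_if_grid_mismatch(richness$grid, m$grid, "category mask")
    sel <- !is.na(m$values) & m$values == 1 & !is.na(richness$values)
    if (!any(sel)) return(NA_real_)
    mean(richness$values[sel])
  }, numeric(1))
}

#' Protection-scenario resampling experiment
#'
#' Estimates the mean richness of a protected-cell sample under three
#' protection scenarios: existing protected areas (`PA`), protected
#' areas plus the strictest refugia (`PA_plus_refugia`), and protected
#' areas plus a random unprotected area equal in cell count to the
#' refugia (`PA_plus_random`, redrawn uniformly every replicate). Each
#' replicate samples `n_cells` cells without replacement from the
#' scenario's pool and averages richness; the default design is 1000
#' cells x 100 replicates.
#'
#' @param richness Richness `pr_raster`.
#' @param pa Protected-area `pr_mask`.
#' @param refugium Strictest refugia `pr_mask`.
#' @param n_cells Cells sampled per replicate.
#' @param n_reps Number of replicates.
#' @param seed Integer seed; identical seeds give identical per-replicate
#'   means.
#' @return Named list of scenario results, each with `scenario`, `means`
#'   (per replicate), `grand_mean`, `sd`.
#' @export
protection_scenarios <- function(richness, pa, refugium,
                                 n_cells = 1000, n_reps = 100, seed = 1) {
  stop_if_grid_mismatch(richness$grid, pa$grid, "protected-area mask")
  stop_if_grid_mismatch(richness$grid, refugium$grid, "refugium mask")
  ok <- !is.na(richness$values)
  pa_cells <- which(ok & !is.na(pa$values) & pa$values == 1)
  ref_cells <- which(ok & !is.na(refugium$values) & refugium$values == 1)
  unprot <- which(ok & !(seq_along(richness$values) %in% pa_cells))
  pools <- list(PA = pa_cells,
                PA_plus_refugia = union(pa_cells, ref_cells))
  n_random <- length(ref_cells)
  sizes <- c(vapply(pools, length, integer(1)),
             PA_plus_random = length(pa_cells) +
               min(n_random, length(unprot)))
  short <- names(sizes)[sizes < n_cells]
  if (length(short))
    stop("scenario pool smaller than n_cells: ",
         paste(short, collapse = ", "))
  if (n_random > length(unprot))
    stop("not enough unprotected cells for the random-area scenario")
  set.seed(seed)
  rich <- richness$values
  run <- function(pool_fn) {
    means <- vapply(seq_len(n_reps), function(r) {
      pool <- pool_fn()
      mean(rich[sample(pool, n_cells)])
    }, numeric(1))
    list(means = means, grand_mean = mean(means), sd = stats::sd(means))
  }
  out <- list(
    PA = run(function() pools$PA),
    PA_plus_refugia = run(function() pools$PA_plus_refugia),
    PA_plus_random = run(function()
      union(pa_cells, sample(unprot, n_random))))
  for (nm in names(out)) out[[nm]]$scenario <- nm
  out
}
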