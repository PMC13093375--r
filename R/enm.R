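# Map point coordinates to (row, col) cell indices on a grid.
points_to_cells <- function(grid, pts) {
  col <- floor((pts[, 1] - grid$origin_x) / grid$cell_size) + 1L
  row <- floor((grid$origin_y - pts[, 2]) / grid$cell_size) + 1L
  ok <- row >= 1 & row <= grid$n_rows & col >= 1 & col <= grid$n_cols
  if (!all(ok)) stop(sum(!ok), " point(s) fall outside the grid")
  cbind(row = row, col = col)
}

# Linear + quadratic design matrix from named climate layers, evaluated
# at cell index rows; column order is var, var^2 per variable.
enm_features <- function(layers, cells) {
  cols <- lapply(names(layers), function(v) {
    x <- layers[[v]]$values[cells]
    cbind(x, x^2)
  })
  X <- do.call(cbind, cols)
  colnames(X) <- as.vector(vapply(names(layers),
                                  function(v) c(v, paste0(v, "^2")),
                                  character(2)))
  X
}

#' Fit a maximum-entropy-style niche model
#'
#' A transparent surrogate for the Maxent workflow: ridge-penalized
#' logistic regression (via glmnet) of presences against a uniform
#' background sample, on standardized linear + quadratic climate
#' features. Suitability is the logistic output in \[0, 1\]. Models are
#' screened exactly as in the study workflow: species with 10 or fewer
#' unique records are rejected (`rejected_records`), and models with
#' AUC <= 0.70 are rejected (`rejected_auc`). The binarization threshold
#' is the 95% minimum-occurrence (5th percentile) suitability at the
#' occurrence points, computed once from the contemporary fit and then
#' frozen for every hindcast slice.
#'
#' @param occurrences A `pr_occurrences` object.
#' @param climate Named list of contemporary climate `pr_raster`s on one
#'   grid (e.g. BIO1, BIO12).
#' @param n_background Number of background cells drawn uniformly (with
#'   replacement) from non-nodata cells; default 10000.
#' @param reg Ridge penalty weight on the standardized scale, expressed
#'   for the summed log-likelihood (glmnet's per-observation lambda is
#'   `reg / n`); default 1.0.
#' @param seed Seed for the background draw.
#' @return A `pr_enm` object with fields `species`, `status`,
#'   `coefficients`, `feature_means`, `feature_sds`, `variables`,
#'   `threshold`, `auc`, `n_presence`, `n_background`.
#' @export
fit_enm <- function(occurrences, climate, n_background = 10000,
                    reg = 1.0, seed = 1) {
  stopifnot(inherits(occurrences, "pr_occurrences"))
  grid <- climate[[1]]$grid
  for (l in climate) stop_if_grid_mismatch(grid, l$grid, l$variable)
  if (!occurrences$modelable)
    return(structure(list(species = occurrences$species,
                          status = "rejected_records",
                          coefficients = NULL,
                          n_presence = occurrences$n_unique),
                     class = "pr_enm"))
  for (l in climate) {
    v <- l$values[!is.na(l$values)]
    if (stats::sd(v) == 0)
      stop("climate layer ", l$variable, " has zero variance")
  }
  set.seed(seed)
  valid <- which(!is.na(climate[[1]]$values) &
                   Reduce(`&`, lapply(climate, function(l) !is.na(l$values))))
  bg_idx <- sample(valid, n_background, replace = TRUE)
  pres_cells <- points_to_cells(grid, occurrences$points)
  pres_idx <- (pres_cells[, "col"] - 1L) * grid$n_rows + pres_cells[, "row"]

  X <- rbind(enm_features(climate, pres_idx),
             enm_features(climate, bg_idx))
  y <- c(rep(1, length(pres_idx)), rep(0, length(bg_idx)))
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd)
  if (any(sg == 0)) stop("degenerate (zero-variance) feature")
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  n <- nrow(Xs)
  lam <- reg / n
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                        lambda = c(lam * 100, lam * 10, lam),
                        standardize = FALSE, thresh = 1e-12)
  beta <- as.numeric(stats::coef(fit, s = lam, exact = FALSE))
  names(beta) <- c("(Intercept)", colnames(X))

  model <- structure(
    list(species = occurrences$species, status = "accepted",
         coefficients = beta, feature_means = mu, feature_sds = sg,
         variables = names(climate),
         n_presence = length(pres_idx), n_background = n_background),
    class = "pr_enm")
  pres_scores <- predict_enm_idx(model, climate, pres_idx)
  bg_scores <- predict_enm_idx(model, climate, bg_idx)
  model$auc <- evaluate_auc(pres_scores, bg_scores)
  model$threshold <- minimum_occurrence_threshold(pres_scores)
  if (model$auc <= 0.70) model$status <- "rejected_auc"
  model
}

# Suitability at a vector of cell indices.
predict_enm_idx <- function(model, layers, idx) {
  X <- enm_features(layers[model$variables], idx)
  Xs <- sweep(sweep(X, 2, model$feature_means), 2, model$feature_sds, "/")
  eta <- drop(model$coefficients[1] + Xs %*% model$coefficients[-1])
  stats::plogis(eta)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen presence score exceeds a
#' randomly chosen background score, with ties counted as one half.
#' Invariant under any strictly increasing transform of the scores.
#'
#' @param presence_scores,background_scores Nonempty numeric vectors.
#' @return AUC in \[0, 1\].
#' @export
evaluate_auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n0 <- length(background_scores)
  if (n1 == 0 || n0 == 0) stop("both score sets must be nonempty")
  r <- rank(c(presence_scores, background_scores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' 95% minimum-occurrence suitability threshold
#'
#' Nearest-rank lower percentile of the suitability scores at occurrence
#' points: sort ascending and take the value at rank
#' `ceiling(percentile/100 * n)`. With the default 5th percentile, at
#' least 95% of occurrence scores are greater than or equal to the
#' threshold. Ties at the threshold count as suitable.
#'
#' @param suitability_at_occurrences Nonempty numeric vector.
#' @param percentile Lower percentile in percent (default 5).
#' @return The threshold value.
#' @export
minimum_occurrence_threshold <- function(suitability_at_occurrences,
                                         percentile = 5) {
  v <- suitability_at_occurrences
  if (length(v) == 0) stop("need at least one suitability value")
  s <- sort(v)
  s[max(1L, ceiling(percentile / 100 * length(s)))]
}

#' Project a fitted niche model onto a climate slice
#'
#' Standardization constants are frozen from fitting; no
#' re-standardization per slice, so hindcasts are strictly comparable
#' through time. Works for any slice whose layers carry the model's
#' variables on the fitting grid.
#'
#' @param model An accepted `pr_enm`.
#' @param layers Named list of climate `pr_raster`s for one time slice.
#' @return Suitability `pr_raster` in \[0, 1\].
#' @export
project_enm <- function(model, layers) {
  if (is.null(model$coefficients))
    stop("cannot project a model with status ", model$status)
  miss <- setdiff(model$variables, names(layers))
  if (length(miss))
    stop("slice is missing variable(s): ", paste(miss, collapse = ", "))
  grid <- layers[[model$variables[1]]]$grid
  for (v in model$variables)
    stop_if_grid_mismatch(grid, layers[[v]]$grid, v)
  na <- Reduce(`|`, lapply(layers[model$variables],
                           function(l) is.na(l$values)))
  idx <- which(!na)
  out <- matrix(NA_real_, grid$n_rows, grid$n_cols)
  out[idx] <- predict_enm_idx(model, layers, idx)
  pr_raster(grid, out, paste0("suitability_", model$species))
}

#' Binarize a suitability surface
#'
#' @param suitability A suitability `pr_raster`.
#' @param threshold Cutoff in \[0, 1\]; cells with suitability `>=`
#'   threshold become 1 (ties count as suitable). Nodata propagates.
#' @return A `pr_mask` with role `"range"`.
#' @export
binarize <- function(suitability, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  pr_mask(suitability$grid, (suitability$values >= threshold) * 1,
          role = "range")
}

#' Restrict a suitability surface to a buffer around a range map
#'
#' Cells whose centers are farther than `buffer_km` (center-to-center
#' Euclidean distance) from every range cell are set to 0, emulating the
#' study's restriction of projections to a 100 km buffer around each
#' species' published range map. Requires a metric CRS.
#'
#' @param suitability A `pr_raster`.
#' @param range_mask A `pr_mask` of the species' range on the same grid.
#' @param buffer_km Buffer radius in the grid's distance units
#'   (default 100).
#' @return The restricted suitability `pr_raster`.
#' @export
buffer_restrict <- function(suitability, range_mask, buffer_km = 100) {
  stop_if_grid_mismatch(suitability$grid, range_mask$grid, "range mask")
  stop_if_geographic(suitability$grid, "buffer_restrict")
  if (!any(range_mask$values == 1, na.rm = TRUE)) {
    warning("empty range mask: restricted suitability is all zero")
    out <- suitability$values
    out[!is.na(out)] <- 0
    return(pr_raster(suitability$grid, out, suitability$variable))
  }
  d <- mask_distance_values(range_mask)
  out <- suitability$values
  out[d > buffer_km & !is.na(out)] <- 0
  pr_raster(suitability$grid, out, suitability$variable)
}
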