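#' Assemble a per-cell analysis table from raster layers
#'
#' One row per cell that is non-nodata in every supplied layer
#' (complete cases), with cell indices and coordinates — the sampling
#' units for all regressions.
#'
#' @param layers Named list of `pr_raster`s on one grid; names become
#'   column names.
#' @return Data frame with columns `row`, `col`, `x`, `y` and one column
#'   per layer.
#' @export
build_cell_table <- function(layers) {
  stopifnot(length(layers) > 0, !is.null(names(layers)))
  grid <- layers[[1]]$grid
  for (l in layers) stop_if_grid_mismatch(grid, l$grid, l$variable)
  cc <- cell_centers(grid)
  idx <- cbind(cc$row, cc$col)
  df <- cc
  for (nm in names(layers)) df[[nm]] <- layers[[nm]]$values[idx]
  df[stats::complete.cases(df), , drop = FALSE]
}

#' Pairwise Pearson collinearity screen
#'
#' @param table Data frame of cells.
#' @param predictors Column names to screen (need >= 3 complete rows).
#' @param cutoff Absolute correlation above which a pair is flagged
#'   (default 0.7, just above the study's observed maximum of 0.69).
#' @return List with the full symmetric correlation `matrix` and a data
#'   frame `flagged` of pairs with `|r| > cutoff`.
#' @export
pearson_screen <- function(table, predictors, cutoff = 0.7) {
  X <- table[, predictors, drop = FALSE]
  if (nrow(X) < 3) stop("need at least 3 complete rows")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(predictors[sds == 0], collapse = ", "))
  m <- stats::cor(X)
  pairs <- which(upper.tri(m) & abs(m) > cutoff, arr.ind = TRUE)
  flagged <- data.frame(var1 = predictors[pairs[, 1]],
                        var2 = predictors[pairs[, 2]],
                        r = m[pairs])
  list(matrix = m, flagged = flagged)
}

# z-standardize selected columns of a table (mean 0, SD 1).
standardize_cols <- function(table, cols) {
  for (cn in cols) {
    x <- table[[cn]]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) stop("cannot standardize constant column ", cn)
    table[[cn]] <- (x - mean(x)) / s
  }
  table
}

# Wrap an lm fit into the package's regression-result structure.
regression_result <- function(fit, kind, predictors) {
  sm <- summary(fit)
  co <- sm$coefficients
  keep <- intersect(rownames(co), predictors)
  structure(list(
    kind = kind,
    coefficients = data.frame(term = keep,
                              estimate = co[keep, "Estimate"],
                              p_value = co[keep, "Pr(>|t|)"],
                              row.names = NULL),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    aic = stats::AIC(fit),
    n = length(fit$residuals),
    fit = fit),
    class = "pr_regression")
}

#' Ordinary least squares on standardized data
#'
#' Response and predictors are z-scored before fitting, so estimates are
#' standardized coefficients; for a univariate fit, R-squared equals the
#' squared coefficient (and the squared Pearson correlation). AIC uses
#' the Gaussian log-likelihood with estimated variance; the intercept is
#' always included and never penalized away.
#'
#' @param table Data frame of complete-case cells.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names.
#' @return A `pr_regression` with standardized `coefficients`
#'   (estimates, two-sided p-values), `r2`, `adj_r2`, `aic`, `n`.
#' @export
fit_ols <- function(table, response, predictors) {
  if (nrow(table) <= length(predictors) + 1)
    stop("need n > p + 1 rows")
  d <- standardize_cols(table[, c(response, predictors), drop = FALSE],
                        c(response, predictors))
  f <- stats::as.formula(paste(response, "~",
                               paste(predictors, collapse = " + ")))
  fit <- stats::lm(f, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design in fit_ols")
  regression_result(fit, "OLS", predictors)
}

#' Spatial weights on grid cells
#'
#' Queen (8-neighbor) or rook (4-neighbor) contiguity on the analysis
#' grid, or symmetric k-nearest-neighbor adjacency; row-standardized by
#' default so each cell's lag is the neighbor mean. Cells with no
#' neighbor (islands) are allowed with a warning and get an all-zero
#' row.
#'
#' @param cells Data frame with integer `row`, `col` columns (e.g. from
#'   [build_cell_table()]).
#' @param scheme `"queen"`, `"rook"` or `"knn"`.
#' @param k Neighbor count for `"knn"`.
#' @param row_standardize Logical; divide each row by its sum.
#' @return A `pr_weights` list: sparse matrix `W` (cells x cells, in
#'   table row order), `scheme`, `row_standardized`.
#' @export
build_weights <- function(cells, scheme = c("queen", "rook", "knn"),
                          k = 8, row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 cells")
  if (scheme %in% c("queen", "rook")) {
    offs <- if (scheme == "queen")
      cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
            dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
    else cbind(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
    key <- function(r, c) paste(r, c)
    index <- stats::setNames(seq_len(n), key(cells$row, cells$col))
    ii <- integer(0); jj <- integer(0)
    for (o in seq_len(nrow(offs))) {
      nb <- index[key(cells$row + offs[o, 1], cells$col + offs[o, 2])]
      hit <- !is.na(nb)
      ii <- c(ii, which(hit)); jj <- c(jj, nb[hit])
    }
    W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  } else {
    stopifnot(k >= 1, k < n)
    ii <- integer(0); jj <- integer(0)
    chunk <- max(1L, floor(4e6 / n))
    for (s in seq(1L, n, by = chunk)) {
      e <- min(s + chunk - 1L, n)
      d2 <- outer(cells$row[s:e], cells$row, "-")^2 +
            outer(cells$col[s:e], cells$col, "-")^2
      d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf
      nb <- apply(d2, 1, function(r) order(r)[seq_len(k)])
      ii <- c(ii, rep(s:e, each = k)); jj <- c(jj, as.integer(nb))
    }
    W <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    W <- ((W + Matrix::t(W)) > 0) * 1  # symmetrize the adjacency
  }
  rs <- Matrix::rowSums(W)
  if (any(rs == 0)) warning(sum(rs == 0), " island cell(s) with no neighbor")
  if (row_standardize) {
    nz <- rs > 0
    W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  }
  structure(list(W = W, scheme = scheme, row_standardized = row_standardize),
            class = "pr_weights")
}

#' Spatial lag-of-X (SLX) regression
#'
#' OLS of the standardized response on each standardized predictor plus
#' its spatially lagged copy (`W %*% x`), absorbing spatial
#' autocorrelation in the covariates. Reported coefficients are the
#' direct (non-lag) effects; fit quality is the adjusted R-squared.
#' Lag columns that are constant or aliased (e.g. under all-zero
#' weights) are dropped, in which case the fit reduces to OLS.
#'
#' @param table Data frame of complete-case cells.
#' @param response Response column name.
#' @param predictors Predictor column names.
#' @param W A `pr_weights` indexed to the rows of `table`.
#' @return A `pr_regression` (kind `"SLX"`) with direct-effect
#'   coefficients, lag coefficients in `lag_coefficients`, and
#'   `adj_r2`.
#' @export
fit_slx <- function(table, response, predictors, W) {
  stopifnot(inherits(W, "pr_weights"),
            nrow(W$W) == nrow(table))
  d <- standardize_cols(table[, c(response, predictors), drop = FALSE],
                        c(response, predictors))
  lag_names <- paste0("lag_", predictors)
  for (i in seq_along(predictors)) {
    lx <- as.numeric(W$W %*% d[[predictors[i]]])
    if (stats::sd(lx) > 0) d[[lag_names[i]]] <- lx
  }
  used_lags <- intersect(lag_names, names(d))
  f <- stats::as.formula(paste(
    response, "~", paste(c(predictors, used_lags), collapse = " + ")))
  fit <- stats::lm(f, data = d)
  cf <- stats::coef(fit)
  if (any(is.na(cf[predictors])))
    stop("rank-deficient design in fit_slx")
  res <- regression_result(fit, "SLX", predictors)
  sm <- summary(fit)$coefficients
  keep <- intersect(rownames(sm), used_lags)
  res$lag_coefficients <- data.frame(term = keep,
                                     estimate = sm[keep, "Estimate"],
                                     p_value = sm[keep, "Pr(>|t|)"],
                                     row.names = NULL)
  res
}

#' Forward stepwise selection by AIC
#'
#' Starting from the intercept-only model, repeatedly adds the candidate
#' whose inclusion most decreases the AIC; stops when no addition
#' decreases it. Ties break deterministically by candidate list order.
#'
#' @param table Data frame of complete-case cells.
#' @param response Response column name.
#' @param candidates Candidate predictor column names.
#' @return List with `selected` (possibly empty character vector) and
#'   `result` (`pr_regression` of the final model; `NULL` when empty).
#' @export
stepwise_aic <- function(table, response, candidates) {
  d <- standardize_cols(table[, c(response, candidates), drop = FALSE],
                        c(response, candidates))
  selected <- character(0)
  current_aic <- stats::AIC(stats::lm(
    stats::as.formula(paste(response, "~ 1")), data = d))
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    aics <- vapply(remaining, function(cand) {
      f <- stats::as.formula(paste(
        response, "~", paste(c(selected, cand), collapse = " + ")))
      stats::AIC(stats::lm(f, data = d))
    }, numeric(1))
    best <- which.min(aics)  # first index wins ties
    if (aics[best] >= current_aic) break
    selected <- c(selected, remaining[best])
    current_aic <- aics[best]
  }
  result <- if (length(selected))
    fit_ols(table, response, selected) else NULL
  list(selected = selected, result = result)
}

#' Distance-decay regressions of a diversity metric
#'
#' OLS and SLX fits of a diversity metric on distance from the nearest
#' refugium edge, optionally restricted to cells of a (forest) mask —
#' the design that separates past stability from current forest cover:
#' under climate-equilibrium expectations the slope would be flat across
#' contemporary forest, whereas refugium-structured diversity declines
#' with distance.
#'
#' @param table Data frame of complete-case cells (with `row`, `col`).
#' @param metric Diversity metric column name.
#' @param distance Distance column name.
#' @param mask Optional `pr_mask`; only cells where the mask is 1 are
#'   used.
#' @param W Optional `pr_weights` for the (possibly masked) rows; built
#'   as queen contiguity when omitted.
#' @return List with `ols` and `slx` `pr_regression`s.
#' @export
distance_decay <- function(table, metric, distance = "distance_to_refugium",
                           mask = NULL, W = NULL) {
  if (!is.null(mask)) {
    keep <- mask$values[cbind(table$row, table$col)] == 1
    keep[is.na(keep)] <- FALSE
    table <- table[keep, , drop = FALSE]
    if (!is.null(W)) W <- NULL  # row indexing changed; rebuild below
  }
  if (nrow(table) == 0) stop("mask removes all rows")
  if (is.null(W)) W <- build_weights(table, "queen")
  list(ols = fit_ols(table, metric, distance),
       slx = fit_slx(table, metric, distance, W))
}
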