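# Gradient world used across niche-model tests: temperature increases
# left to right, precipitation top to bottom, no noise.
gradient_world <- function(nr = 30, nc = 30) {
  g <- tiny_grid(nr, nc, cell_size = 1)
  list(grid = g,
       layers = list(
         BIO1 = pr_raster(g, matrix(seq(0, 10, length.out = nc),
                                    nr, nc, byrow = TRUE), "BIO1"),
         BIO12 = pr_raster(g, matrix(seq(0, 10, length.out = nr),
                                     nr, nc), "BIO12")))
}

occ_at_cells <- function(grid, rows, cols, species = "sp") {
  cc <- cell_centers(grid)
  idx <- match(paste(rows, cols), paste(cc$row, cc$col))
  structure(list(species = species,
                 points = as.matrix(cc[idx, c("x", "y")]),
                 n_unique = length(idx), modelable = length(idx) > 10),
            class = "pr_occurrences")
}

test_that("AUC is the Mann-Whitney probability with ties at one half", {
  expect_equal(evaluate_auc(c(5, 6, 7), c(1, 2, 3)), 1.0)
  expect_equal(evaluate_auc(rep(2, 4), rep(2, 6)), 0.5)
  # enumerate the 4 pairs: 0.9 beats both; 0.8 beats 0.7, loses to 0.85
  expect_equal(evaluate_auc(c(0.9, 0.8), c(0.7, 0.85)), 0.75)
  expect_error(evaluate_auc(numeric(0), 1), "nonempty")
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(1)
  p <- runif(40); b <- runif(60)
  a0 <- evaluate_auc(p, b)
  expect_equal(evaluate_auc(exp(3 * p), exp(3 * b)), a0)
  expect_equal(evaluate_auc(qlogis(p), qlogis(b)), a0)
})

test_that("minimum-occurrence threshold uses the nearest-rank percentile", {
  vals <- seq(0.05, 1, by = 0.05)           # 20 values
  expect_equal(minimum_occurrence_threshold(vals), 0.05)  # rank ceil(1)=1
  expect_equal(minimum_occurrence_threshold(rep(0.4, 7)), 0.4)
  expect_equal(minimum_occurrence_threshold(0.83), 0.83)
  # 21 values: rank ceil(1.05) = 2
  expect_equal(minimum_occurrence_threshold(1:21 / 21), 2 / 21)
  expect_error(minimum_occurrence_threshold(numeric(0)), "at least one")
})

test_that("threshold guarantees at least 95% occurrence coverage", {
  set.seed(42)
  for (i in 1:1000) {
    v <- runif(sample(1:60, 1))
    thr <- minimum_occurrence_threshold(v)
    expect_gte(mean(v >= thr), 0.95)
  }
})

test_that("fitted response increases along a gradient that presences track", {
  w <- gradient_world()
  # presences confined to the hottest third of columns
  set.seed(2)
  rows <- sample(1:30, 40, replace = TRUE)
  cols <- sample(21:30, 40, replace = TRUE)
  m <- fit_enm(occ_at_cells(w$grid, rows, cols), w$layers,
               n_background = 500, seed = 1)
  expect_equal(m$status, "accepted")
  suit <- project_enm(m, w$layers)
  profile <- colMeans(suit$values)
  # response strictly increasing over the observed temperature range
  expect_true(all(diff(profile[10:30]) > 0))
  expect_gt(m$auc, 0.7)
})

test_that("random presences fail the AUC screen", {
  w <- gradient_world()
  set.seed(3)
  rows <- sample(1:30, 500, replace = TRUE)
  cols <- sample(1:30, 500, replace = TRUE)
  occ <- occ_at_cells(w$grid, rows, cols)
  occ$points <- unique(occ$points); occ$n_unique <- nrow(occ$points)
  m <- fit_enm(occ, w$layers, n_background = 1000, seed = 1)
  expect_gt(m$auc, 0.4); expect_lt(m$auc, 0.6)
  expect_equal(m$status, "rejected_auc")
})

test_that("too few records short-circuits fitting", {
  w <- gradient_world()
  m <- fit_enm(occ_at_cells(w$grid, 1:5, 1:5), w$layers)
  expect_equal(m$status, "rejected_records")
  expect_null(m$coefficients)
  expect_error(project_enm(m, w$layers), "rejected_records")
})

test_that("heavy ridge regularization flattens the response", {
  w <- gradient_world()
  set.seed(4)
  rows <- sample(1:30, 40, replace = TRUE)
  cols <- sample(21:30, 40, replace = TRUE)
  occ <- occ_at_cells(w$grid, rows, cols)
  m <- fit_enm(occ, w$layers, n_background = 500, reg = 1e9, seed = 1)
  expect_lt(max(abs(m$coefficients[-1])), 1e-4)
  suit <- project_enm(m, w$layers)
  expect_lt(diff(range(suit$values)), 1e-3)
})

test_that("degenerate climate is rejected", {
  g <- tiny_grid(10, 10)
  flat <- list(BIO1 = pr_raster(g, matrix(5, 10, 10), "BIO1"),
               BIO12 = pr_raster(g, matrix(seq(0, 1, length.out = 100),
                                           10, 10), "BIO12"))
  occ <- occ_at_cells(g, rep(1:4, 3), rep(1:4, each = 3))
  expect_error(fit_enm(occ, flat, n_background = 50), "zero variance")
})

test_that("projection is deterministic, bounded and frozen-standardized", {
  w <- gradient_world()
  set.seed(5)
  occ <- occ_at_cells(w$grid, sample(10:20, 30, TRUE), sample(10:20, 30, TRUE))
  m <- fit_enm(occ, w$layers, n_background = 500, seed = 2)
  s1 <- project_enm(m, w$layers)
  s2 <- project_enm(m, w$layers)
  expect_identical(s1$values, s2$values)
  # extreme climates stay in [0, 1] and never NaN
  extreme <- list(BIO1 = pr_raster(w$grid, matrix(1e3, 30, 30), "BIO1"),
                  BIO12 = pr_raster(w$grid, matrix(-1e3, 30, 30), "BIO12"))
  se <- project_enm(m, extreme)
  expect_true(all(is.finite(se$values)))
  expect_true(all(se$values >= 0 & se$values <= 1))
  expect_error(project_enm(m, w$layers["BIO1"]), "missing variable")
})

test_that("binarize thresholds with ties counted as suitable", {
  g <- tiny_grid(2, 2)
  suit <- pr_raster(g, matrix(c(0.2, 0.7, 0.5, 0.4), 2, 2))
  expect_equal(binarize(suit, 0.5)$values, matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sum(binarize(suit, 0)$values), 4)
  expect_equal(sum(binarize(suit, 0.9)$values), 0)
  na <- pr_raster(g, matrix(c(NA, 0.7, 0.5, 0.4), 2, 2))
  expect_true(is.na(binarize(na, 0.5)$values[1, 1]))
})

test_that("binarized projections are nested in the threshold", {
  w <- gradient_world()
  set.seed(6)
  occ <- occ_at_cells(w$grid, sample(5:25, 30, TRUE), sample(5:25, 30, TRUE))
  m <- fit_enm(occ, w$layers, n_background = 300, seed = 3)
  suit <- project_enm(m, w$layers)
  loose <- binarize(suit, 0.2)$values
  strict <- binarize(suit, 0.6)$values
  expect_true(all(loose >= strict))
})

test_that("buffer restriction keeps exactly the cells within reach", {
  g <- tiny_grid(9, 9, cell_size = 4.5)
  rng <- matrix(0, 9, 9); rng[5, 5] <- 1
  suit <- pr_raster(g, matrix(1, 9, 9))
  kept <- buffer_restrict(suit, pr_mask(g, rng), buffer_km = 10)
  # brute-force oracle over all 81 cells
  d <- sqrt(outer((1:9 - 5)^2, (1:9 - 5)^2, "+")) * 4.5
  expect_equal(kept$values, (d <= 10) * 1)
  expect_equal(sum(kept$values), 13)
  # zero buffer keeps only range cells; huge buffer keeps everything
  expect_equal(buffer_restrict(suit, pr_mask(g, rng), 0)$values, rng)
  expect_equal(buffer_restrict(suit, pr_mask(g, rng), 1e4)$values,
               suit$values)
  expect_warning(
    empty <- buffer_restrict(suit, pr_mask(g, matrix(0, 9, 9)), 10),
    "empty range mask")
  expect_equal(sum(empty$values), 0)
})

test_that("niche optima are recovered on correctly specified synthetic species", {
  cfg <- sim_config(seed = 13, n_rows = 40, n_cols = 40,
                    core_rows = 14:27, core_cols = 14:27,
                    S_indicator = 5, S_focal = 15,
                    start_age = 120, end_age = 20, step = 10,
                    n_occurrences = 200)
  clim <- simulate_climate_history(cfg)
  sp <- simulate_species(cfg, clim)
  grad <- list(BIO1 = clim$contemporary$BIO1, BIO12 = clim$contemporary$BIO12)
  hits <- 0; total <- 0
  for (nm in names(sp$truth)) {
    m <- fit_enm(sp$occurrences[[nm]], grad, n_background = 2000,
                 seed = 1)
    if (!identical(m$status, "accepted")) next
    suit <- project_enm(m, grad)
    best <- which(suit$values == max(suit$values), arr.ind = TRUE)[1, ]
    est <- c(grad$BIO1$values[best[1], best[2]],
             grad$BIO12$values[best[1], best[2]])
    err <- sqrt(sum((est - sp$truth[[nm]]$niche_optimum)^2))
    total <- total + 1
    if (err <= 0.5 * cfg$niche_breadth) hits <- hits + 1
  }
  expect_gte(total, 10)
  expect_gte(hits / total, 0.9)
})
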