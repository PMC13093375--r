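grid_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  d <- expand.grid(row = 1:n, col = 1:n)
  d$x <- d$col - 0.5; d$y <- n - d$row + 0.5
  d
}

test_that("Pearson screen flags strong pairs and validates input", {
  d <- data.frame(x = c(1, 2, 3), z = c(1, 2, 4))
  d$negx <- -d$x
  out <- pearson_screen(d, c("x", "z", "negx"))
  expect_equal(out$matrix["x", "x"], 1)
  expect_equal(out$matrix["x", "z"], 0.9820, tolerance = 1e-4)
  expect_equal(out$matrix["x", "negx"], -1)
  expect_true(any(out$flagged$var1 == "x" & out$flagged$var2 == "negx"))
  d$flat <- 1
  expect_error(pearson_screen(d, c("x", "flat")), "zero-variance")
  expect_error(pearson_screen(d[1:2, ], c("x", "z")), "3 complete rows")
})

test_that("standardized univariate OLS has R2 equal to squared Pearson r", {
  set.seed(4)
  for (i in 1:20) {
    d <- data.frame(x = rnorm(40))
    d$y <- 0.6 * d$x + rnorm(40, sd = runif(1, 0.1, 2))
    fit <- fit_ols(d, "y", "x")
    r <- cor(d$x, d$y)
    expect_equal(fit$r2, r^2, tolerance = 1e-10)
    expect_equal(fit$coefficients$estimate, r, tolerance = 1e-10)
    expect_equal(fit$r2, fit$coefficients$estimate^2, tolerance = 1e-10)
  }
})

test_that("OLS reproduces exact fits and matches normal equations", {
  d <- data.frame(x = rnorm(30)); d$y <- d$x
  fit <- suppressWarnings(fit_ols(d, "y", "x"))  # exact fit by design
  expect_equal(fit$coefficients$estimate, 1, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # independent normal-equations solution on random small designs
  set.seed(9)
  for (i in 1:10) {
    n <- sample(20:50, 1); p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    d <- as.data.frame(scale(cbind(y = y, X)))
    names(d) <- c("y", paste0("x", 1:p))
    Xs <- cbind(1, as.matrix(d[, -1]))
    beta <- solve(t(Xs) %*% Xs, t(Xs) %*% d$y)
    fit <- fit_ols(d, "y", paste0("x", 1:p))
    expect_equal(fit$coefficients$estimate, beta[-1, 1], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("null coefficients are near zero at large n", {
  set.seed(11)
  d <- data.frame(x = rnorm(10000), y = rnorm(10000))
  fit <- fit_ols(d, "y", "x")
  expect_lt(abs(fit$coefficients$estimate), 0.05)
  expect_error(fit_ols(d[1:2, ], "y", "x"), "n > p")
})

test_that("queen and rook weights enumerate grid neighbors", {
  d <- grid_table(4)
  q <- build_weights(d, "queen", row_standardize = FALSE)
  # interior cell (2,2) -> 8 neighbors; corner (1,1) -> 3
  interior <- which(d$row == 2 & d$col == 2)
  corner <- which(d$row == 1 & d$col == 1)
  expect_equal(Matrix::rowSums(q$W)[interior], 8)
  expect_equal(Matrix::rowSums(q$W)[corner], 3)
  expect_true(Matrix::isSymmetric(q$W))
  qs <- build_weights(d, "queen")
  expect_equal(unname(Matrix::rowSums(qs$W)[interior]), 1)
  expect_equal(unname(qs$W[corner, ])[qs$W[corner, ] > 0], rep(1 / 3, 3))
  # 1xn strip under rook: interior cells have 2 neighbors
  strip <- data.frame(row = 1, col = 1:6)
  r <- build_weights(strip, "rook", row_standardize = FALSE)
  expect_equal(unname(Matrix::rowSums(r$W)), c(1, 2, 2, 2, 2, 1))
  expect_error(build_weights(strip[1, , drop = FALSE]), "at least 2")
})

test_that("knn weights are symmetric and islands warned", {
  d <- grid_table(5)
  k <- build_weights(d, "knn", k = 4, row_standardize = FALSE)
  expect_true(Matrix::isSymmetric(k$W))
  expect_true(all(Matrix::rowSums(k$W) >= 4))
  far <- data.frame(row = c(1, 1, 50), col = c(1, 2, 50))
  expect_warning(build_weights(far, "queen"), "island")
})

test_that("SLX reduces to OLS under empty weights and bounds adj R2", {
  set.seed(13)
  d <- grid_table(8)
  d$x <- rnorm(64); d$y <- 0.5 * d$x + rnorm(64)
  W0 <- build_weights(d, "queen")
  W0$W <- W0$W * 0
  slx0 <- fit_slx(d, "y", "x", W0)
  ols <- fit_ols(d, "y", "x")
  expect_equal(slx0$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(slx0$r2, ols$r2, tolerance = 1e-12)
  expect_equal(logLik(slx0$fit), logLik(ols$fit))
  W <- build_weights(d, "queen")
  slx <- fit_slx(d, "y", "x", W)
  expect_lte(slx$adj_r2, 1)
  expect_equal(nrow(slx$lag_coefficients), 1)
})

test_that("SLX recovers a direct effect with a null lag on smooth fields", {
  set.seed(17)
  d <- grid_table(50)   # 2500 cells
  d$x <- sin(d$row / 6) + cos(d$col / 5) + rnorm(2500, sd = 0.3)
  d$y <- d$x + rnorm(2500, sd = 0.1)
  W <- build_weights(d, "queen")
  slx <- fit_slx(d, "y", "x", W)
  expect_gt(slx$coefficients$estimate, 0.9)
  expect_lt(slx$coefficients$estimate, 1.1)
  expect_lt(abs(slx$lag_coefficients$estimate), 0.1)
})

test_that("forward AIC keeps exact predictors and drops pure noise order-free", {
  set.seed(19)
  d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  d$y <- d$x1
  out <- suppressWarnings(stepwise_aic(d, "y", c("x1", "x2")))
  expect_equal(out$selected, "x1")
  rev_out <- suppressWarnings(stepwise_aic(d, "y", c("x2", "x1")))
  expect_equal(sort(rev_out$selected), sort(out$selected))
  expect_s3_class(out$result, "pr_regression")
})

test_that("stepwise on pure noise usually selects the empty model", {
  set.seed(23)
  empty <- 0
  for (r in 1:100) {
    d <- data.frame(x = rnorm(2000), y = rnorm(2000))
    out <- stepwise_aic(d, "y", "x")
    if (length(out$selected) == 0) empty <- empty + 1
  }
  # AIC admits a null predictor only when its chi-square(1) deviance
  # improvement exceeds 2, i.e. ~15.7% of the time
  expect_gte(empty, 75)
  expect_lte(empty, 95)
})

test_that("distance decay handles degenerate and exact relationships", {
  d <- grid_table(10)
  d$dist <- sqrt((d$row - 5)^2 + (d$col - 5)^2)
  d$flat <- 1 + 0 * d$dist
  expect_error(fit_ols(d, "flat", "dist"), "constant column")
  d$metric <- -d$dist
  dd <- suppressWarnings(distance_decay(d, "metric", "dist"))
  expect_equal(dd$ols$coefficients$estimate, -1, tolerance = 1e-10)
  expect_equal(dd$ols$r2, 1, tolerance = 1e-10)
  # masked variant restricts rows
  g <- tiny_grid(10, 10)
  m <- matrix(0, 10, 10); m[1:5, ] <- 1
  dd_m <- suppressWarnings(
    distance_decay(d, "metric", "dist", mask = pr_mask(g, m)))
  expect_equal(dd_m$ols$n, 50)
  empty_mask <- pr_mask(g, matrix(0, 10, 10))
  expect_error(distance_decay(d, "metric", "dist", mask = empty_mask),
               "removes all rows")
})

test_that("standardization round-trips fitted coefficients", {
  set.seed(29)
  d <- data.frame(x = rnorm(100, 50, 9), z = rnorm(100, -3, 0.5))
  d$y <- 2 * d$x - 4 * d$z + rnorm(100)
  fit <- fit_ols(d, "y", c("x", "z"))
  # destandardize, then restandardize: b_raw = b_std * sd(y)/sd(x)
  b_std <- fit$coefficients$estimate
  b_raw <- b_std * sd(d$y) / c(sd(d$x), sd(d$z))
  expect_equal(b_raw * c(sd(d$x), sd(d$z)) / sd(d$y), b_std,
               tolerance = 1e-10)
  raw_fit <- lm(y ~ x + z, data = d)
  expect_equal(b_raw, unname(coef(raw_fit)[-1]), tolerance = 1e-10)
})
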