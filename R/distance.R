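# Exact Euclidean distance transform (Felzenszwalb & Huttenlocher),
# separable 1-D lower-envelope passes over columns then rows. Distances
# are center-to-center; O(cells) per mask, replacing an all-pairs scan.

# 1-D squared-distance transform: D(i) = min_j f(j) + (i - j)^2.
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L; z[1L] <- -Inf; z[2L] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Per-cell Euclidean distance (grid distance units) from every cell
# center to the nearest 1-cell of a mask; Inf when the mask is empty.
mask_distance_values <- function(mask) {
  g <- mask$grid
  m <- mask$values
  # large finite stand-in for +Inf keeps the envelope arithmetic clean;
  # any true distance squared is < big, so it never wins.
  big <- 4 * (g$n_rows^2 + g$n_cols^2) + 1
  f <- matrix(big, g$n_rows, g$n_cols)
  f[!is.na(m) & m == 1] <- 0
  if (!any(f == 0)) return(matrix(Inf, g$n_rows, g$n_cols))
  if (g$n_rows > 1) for (j in seq_len(g$n_cols)) f[, j] <- dt1d(f[, j])
  if (g$n_cols > 1) for (i in seq_len(g$n_rows)) f[i, ] <- dt1d(f[i, ])
  sqrt(f) * g$cell_size
}
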