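# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain loops and closed forms only.

# Exhaustive Otsu: maximize the between-class variance by looping over every
# threshold and computing class statistics by subsetting.
otsu_brute <- function(g, L = 256L) {
  v <- as.vector(g)
  mu_t <- mean(v)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:(L - 1L)) {
    c1 <- v[v <= t]; c2 <- v[v > t]
    crit <- if (length(c1) == 0L || length(c2) == 0L) 0 else {
      w1 <- length(c1) / length(v); w2 <- 1 - w1
      w1 * (mean(c1) - mu_t)^2 + w2 * (mean(c2) - mu_t)^2
    }
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  best_t
}

# Quadratic least squares via the normal equations.
quad_fit_brute <- function(x, y) {
  X <- cbind(1, x, x^2)
  as.vector(solve(t(X) %*% X, t(X) %*% y))
}

# Region statistics via an explicit pixel loop.
region_stats_brute <- function(t, mask) {
  vals <- c()
  for (i in seq_len(nrow(t))) for (j in seq_len(ncol(t))) {
    if (mask[i, j]) vals <- c(vals, t[i, j])
  }
  m <- mean(vals)
  list(avg = m, max = max(vals), min = min(vals),
       sd = sqrt(mean((vals - m)^2)), pixel_count = length(vals))
}

random_thermogram <- function(nr = 16, nc = 16, meta = radiometric_meta(24, 36)) {
  thermogram(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc), meta)
}

mirror_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
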