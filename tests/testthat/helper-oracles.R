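# Independent oracles used to cross-check the implementation.

# Natural interpolating cubic spline via the classical tridiagonal system
# for the knot second derivatives (M_1 = M_n = 0), coded independently of
# stats::splinefun.
natural_spline_oracle <- function(x, y) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b)
  function(q) {
    vapply(q, function(xq) {
      i <- findInterval(xq, x, rightmost.closed = TRUE)
      i <- min(max(i, 1L), n - 1L)
      d <- xq - x[i]
      hi <- h[i]
      y[i] +
        d * ((y[i + 1] - y[i]) / hi - hi / 6 * (2 * M[i] + M[i + 1])) +
        d^2 * M[i] / 2 +
        d^3 * (M[i + 1] - M[i]) / (6 * hi)
    }, numeric(1))
  }
}

# Two-pass mean / n-1 SD oracle.
two_pass_stats <- function(d) {
  m <- sum(d) / length(d)
  list(mean = m, sd = sqrt(sum((d - m)^2) / (length(d) - 1)))
}

# Fold-left running mean oracle.
fold_left_mean <- function(x) {
  acc <- 0
  for (i in seq_along(x)) acc <- acc + (x[i] - acc) / i
  acc
}

# Normal-equations least squares oracle.
normal_equations <- function(X, y) solve(t(X) %*% X) %*% t(X) %*% y

# Fine-grid trapezoidal integral of the piecewise-linear knot envelope.
riemann_area <- function(t, a, from, to, n_grid = 2e5) {
  g <- seq(from, to, length.out = n_grid)
  v <- approx(t, a, xout = g)$y
  sum(diff(g) * (head(v, -1) + tail(v, -1)) / 2)
}
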