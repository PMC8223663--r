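# Independent oracles, written without reference to the package internals.

# Penalized log-likelihood l(beta) + 0.5 log|X'WX|, direct implementation.
pll_oracle <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  w <- p * (1 - p)
  I <- crossprod(X * sqrt(w))
  sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus[1]
}

# Brute-force maximization of the penalized likelihood by iteratively
# refined grid search (p = 1 or 2).
grid_firth_oracle <- function(X, y, span = 8, n_refine = 8, grid_n = 21) {
  p <- ncol(X)
  center <- rep(0, p)
  for (it in seq_len(n_refine)) {
    axes <- lapply(seq_len(p), function(j)
      seq(center[j] - span, center[j] + span, length.out = grid_n))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, function(b) pll_oracle(X, y, b))
    center <- grid[which.max(vals), ]
    span <- 2 * (2 * span / (grid_n - 1))   # keep two old grid steps on each side
  }
  unname(center)
}

# Profile penalized likelihood of coefficient j on a dense value grid,
# maximizing over the other coefficient by refined 1-D grid search.
profile_grid_oracle <- function(X, y, j, values, span = 10, n_refine = 8,
                                grid_n = 41) {
  other <- setdiff(seq_len(ncol(X)), j)
  vapply(values, function(v) {
    center <- 0
    s <- span
    for (it in seq_len(n_refine)) {
      g <- seq(center - s, center + s, length.out = grid_n)
      vals <- vapply(g, function(b) {
        beta <- numeric(ncol(X)); beta[j] <- v; beta[other] <- b
        pll_oracle(X, y, beta)
      }, 0)
      center <- g[which.max(vals)]
      s <- 2 * (2 * s / (grid_n - 1))
    }
    beta <- numeric(ncol(X)); beta[j] <- v; beta[other] <- center
    pll_oracle(X, y, beta)
  }, 0)
}

# Haldane half-cell-corrected log odds ratio for a 2x2 table.
haldane_log_or <- function(a, b, c, d) {
  log((a + 0.5) * (d + 0.5) / ((b + 0.5) * (c + 0.5)))
}

# Expand a 2x2 table (exposed-case a, exposed-control b, unexposed-case c,
# unexposed-control d) into a design matrix and response.
design_2x2 <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(X = cbind(intercept = 1, exposure = x), y = y)
}
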