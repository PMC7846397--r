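# Independent oracles used across the suite.

# Explicit orthonormal one-step Haar analysis matrix (pairs average/difference)
haar_matrix <- function(m) {
  H <- matrix(0, m, m)
  for (i in seq_len(m / 2)) {
    H[i, 2 * i - 1] <- H[i, 2 * i] <- 1 / sqrt(2)
    H[m / 2 + i, 2 * i - 1] <- 1 / sqrt(2)
    H[m / 2 + i, 2 * i] <- -1 / sqrt(2)
  }
  H
}

# Multilevel 2-D Haar built from explicit matrices (independent of dwt())
haar2d_oracle <- function(x, level) {
  n <- nrow(x)
  m <- n
  for (l in seq_len(level)) {
    H <- haar_matrix(m)
    x[1:m, 1:m] <- H %*% x[1:m, 1:m] %*% t(H)
    m <- m / 2
  }
  x
}

# Brute-force scalar proximal oracle: grid-search minimiser of
# lam*|a| + (rho/2)*(a - v)^2
prox_oracle <- function(v, lam, rho, step = 1e-4) {
  grid <- seq(-abs(v) - 1, abs(v) + 1, by = step)
  obj <- lam * abs(grid) + rho / 2 * (grid - v)^2
  grid[which.min(obj)]
}

# Naive O(n^4) DC-centred orthonormal DFT for tiny grids
dft_oracle <- function(x) {
  n <- nrow(x)
  idx <- 0:(n - 1)
  W <- exp(-2i * pi * outer(idx, idx) / n)
  k <- (W %*% x %*% W) / n
  # shift DC to centre
  sh <- function(v) c(v[(n / 2 + 1):n], v[1:(n / 2)])
  k[sh(1:n), sh(1:n)]
}

random_image <- function(n, seed = 1) {
  set.seed(seed)
  matrix(stats::runif(n * n), n, n)
}
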