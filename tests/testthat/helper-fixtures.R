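# shared fixtures: all inputs are generated in code at test time

# random irregular geometry: a blob of tissue with random fibre directions
random_geometry <- function(nx = 7, ny = 7, nz = 1, p_tissue = 0.6) {
  repeat {
    status <- array(rbinom(nx * ny * nz, 1, p_tissue), dim = c(nx, ny, nz))
    if (sum(status) >= 2) break
  }
  fib <- array(rnorm(nx * ny * nz * 3), dim = c(nx, ny, nz, 3))
  geometry_grid(nx, ny, nz, h = 0.3, status, fib)
}

# random Markov rate matrix: non-negative off-diagonals, zero column sums
random_rate_matrix <- function(n) {
  M <- matrix(runif(n * n, 0.1, 2), n, n)
  diag(M) <- 0
  diag(M) <- -colSums(M)
  M
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-300), tol)
}
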