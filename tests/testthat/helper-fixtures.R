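# Shared fixtures: small grids, dense-solve oracles, random systems.

tiny_grid <- function(n = 9L, spacing = 1) imaging_grid(n, n, spacing)

# Dense assembly of the same finite-volume operator, built independently
# entry by entry from the stencil definition (oracle for the sparse path).
dense_diffusion_operator <- function(grid, mu_a, D) {
  nx <- grid$nx; ny <- grid$ny; h <- grid$spacing
  N <- nx * ny
  M <- matrix(0, N, N)
  id <- function(ix, iy) (iy - 1L) * nx + ix
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    i <- id(ix, iy)
    nb <- list(c(ix - 1L, iy), c(ix + 1L, iy), c(ix, iy - 1L), c(ix, iy + 1L))
    for (p in nb) {
      if (p[1] >= 1L && p[1] <= nx && p[2] >= 1L && p[2] <= ny) {
        j <- id(p[1], p[2])
        M[i, i] <- M[i, i] + D
        M[i, j] <- M[i, j] - D
      } else {
        M[i, i] <- M[i, i] + h / (2 * grid$robin)  # Robin flux on exposed face
      }
    }
    M[i, i] <- M[i, i] + mu_a * h^2
  }
  M
}

# Full-row-rank random M x N matrix (M <= N) with entries ~ N(0, 1)
random_full_rank <- function(M, N, seed) {
  set.seed(seed)
  matrix(rnorm(M * N), M, N)
}

# Plain-R reference Kaczmarz sweep (independent of the compiled path)
reference_sweep <- function(B, y, x) {
  for (i in seq_len(nrow(B))) {
    bi <- B[i, ]
    n2 <- sum(bi^2)
    if (sqrt(n2) <= 1e-14 * max(sqrt(rowSums(B^2)))) next
    x <- x + bi * (y[i] - sum(bi * x)) / n2
  }
  x
}

# Exhaustive find_beta oracle: try every top-m positive support directly
brute_force_beta <- function(x, psi) {
  vs <- sort(x[x > 0], decreasing = TRUE)
  N <- length(x)
  best <- Inf
  for (m in seq_along(vs)) {
    xt <- x
    xt[xt < vs[m]] <- 0
    s <- (sqrt(N) - sum(abs(xt)) / sqrt(sum(xt^2))) / (sqrt(N) - 1)
    best <- min(best, abs(s - psi))
  }
  best
}
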