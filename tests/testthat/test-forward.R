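test_that("diffusion coefficient follows 1/(3(mu_a + mu_s')) and rejects bad input", {
  # murine muscle and liver excitation-band values
  expect_equal(diffusion_coefficient(0.0052, 1.08), 1 / (3 * 1.0852))
  expect_equal(diffusion_coefficient(0.0329, 0.70), 1 / (3 * 0.7329))
  expect_error(diffusion_coefficient(1 / 3, 0), "invalid parameter")
  expect_error(diffusion_coefficient(-0.1, 1), "invalid parameter")
})

test_that("discrete diffusion operator is symmetric positive definite and matches the dense oracle", {
  for (params in list(list(mu_a = 0.0052, D = 0.307), list(mu_a = 0.066, D = 0.144))) {
    g <- tiny_grid(7L, spacing = 0.5)
    Ms <- as.matrix(scpkaczmarz:::diffusion_operator(g, params$mu_a, params$D))
    Md <- dense_diffusion_operator(g, params$mu_a, params$D)
    expect_equal(Ms, Md, tolerance = 1e-14, ignore_attr = TRUE)
    expect_equal(Ms, t(Ms))
    expect_gt(min(eigen(Ms, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("diffusion field equals the dense direct solve and is strictly positive", {
  g <- tiny_grid(9L)
  src <- source_spec(c(3, 5), amplitude = 2)
  f <- solve_diffusion_field(g, 0.01, 0.3, src)
  Md <- dense_diffusion_operator(g, 0.01, 0.3)
  b <- numeric(81); b[nearest_node(g, c(3, 5))] <- 2
  expect_equal(f$values, drop(solve(Md, b)), tolerance = 1e-12)
  expect_true(all(f$values > 0))
})

test_that("centered source on a symmetric domain gives a reflection-symmetric field", {
  g <- tiny_grid(11L)
  f <- solve_diffusion_field(g, 0.02, 0.25, source_spec(c(5, 5)))
  v <- matrix(f$values, 11, 11)
  expect_lt(max(abs(v - v[11:1, ])), 1e-12)   # mirror in x
  expect_lt(max(abs(v - v[, 11:1])), 1e-12)   # mirror in y
  expect_lt(max(abs(v - t(v))), 1e-12)        # diagonal
})

test_that("sensitivity columns match the brute-force emission-solve oracle", {
  g <- imaging_grid(11L, 11L, 1)
  props <- muscle_optics()
  sources <- list(source_spec(c(2, 2)), source_spec(c(8, 6)))
  det_pos <- grid_coordinates(g)[boundary_nodes(g), ][c(1, 12, 25, 38), ]
  sm <- assemble_sensitivity_matrix(g, props, sources, det_pos)
  expect_true(all(sm$A >= 0))

  # brute force: put unit yield at node j, drive the emission equation with
  # Phi_x * x, read the emission field at the detector nodes
  Mm <- dense_diffusion_operator(g, props$mu_am, props$D_m)
  for (s in 1:2) {
    phi_x <- solve_diffusion_field(g, props$mu_ax, props$D_x, sources[[s]])$values
    for (j in c(1L, 13L, 61L, 111L, 121L)) {
      b <- numeric(121)
      b[j] <- phi_x[j] * g$spacing^2
      phi_m <- solve(Mm, b)
      expected <- phi_m[sm$det_nodes]
      got <- sm$A[(s - 1L) * 4L + 1:4, j]
      expect_lt(max(abs(got - expected)) / max(max(abs(expected)), 1e-300), 1e-10)
    }
  }
})

test_that("swapping two detectors permutes the corresponding rows exactly", {
  g <- imaging_grid(9L, 9L, 1)
  props <- muscle_optics()
  src <- list(source_spec(c(4, 4)))
  dets <- grid_coordinates(g)[boundary_nodes(g), ][c(3, 17, 30), ]
  s1 <- assemble_sensitivity_matrix(g, props, src, dets)
  s2 <- assemble_sensitivity_matrix(g, props, src, dets[c(2, 1, 3), ])
  expect_identical(s1$A[1, ], s2$A[2, ])
  expect_identical(s1$A[2, ], s2$A[1, ])
  expect_identical(s1$A[3, ], s2$A[3, ])
})

test_that("detectors off the boundary are rejected", {
  g <- imaging_grid(9L, 9L, 1)
  expect_error(
    assemble_sensitivity_matrix(g, muscle_optics(), list(source_spec(c(4, 4))),
                                matrix(c(4, 4), 1)),
    "layout error"
  )
})

test_that("reciprocity holds when excitation and emission optics coincide", {
  g <- imaging_grid(9L, 9L, 1)
  props <- optical_properties(0.01, 1.0, 0.01, 1.0)
  bpos <- grid_coordinates(g)[boundary_nodes(g), ]
  pa <- bpos[5, ]; pb <- bpos[20, ]
  # measurement with source at (near) a, detector at b vs roles exchanged
  sa <- assemble_sensitivity_matrix(g, props, list(source_spec(pa)), matrix(pb, 1))
  sb <- assemble_sensitivity_matrix(g, props, list(source_spec(pb)), matrix(pa, 1))
  x <- runif(81)
  expect_equal(drop(sa$A %*% x), drop(sb$A %*% x), tolerance = 1e-10)
})

test_that("measurement simulation is reproducible, exact when noiseless, and checks shapes", {
  A <- random_full_rank(6, 15, seed = 11)
  x <- abs(rnorm(15))
  expect_equal(simulate_measurements(A, x, 0), drop(A %*% x))
  n1 <- simulate_measurements(A, x, 0.05, seed = 42)
  n2 <- simulate_measurements(A, x, 0.05, seed = 42)
  expect_identical(n1, n2)
  expect_false(identical(n1, simulate_measurements(A, x, 0.05, seed = 43)))
  expect_equal(simulate_measurements(A, numeric(15), 0.1, seed = 1), numeric(6))
  expect_error(simulate_measurements(A, numeric(14), 0), "shape error")
})

test_that("sources are placed one transport mean free path beneath the boundary", {
  g <- imaging_grid(21L, 21L, 1)  # domain [0, 20]^2
  mu_s <- 1.08
  srcs <- place_sources(g, 5L, mu_s)
  expect_length(srcs, 5L)
  ext <- c(0, 20, 0, 20)
  for (s in srcs) {
    d <- min(s$position[1] - ext[1], ext[2] - s$position[1],
             s$position[2] - ext[3], ext[4] - s$position[2])
    expect_equal(d, 1 / mu_s, tolerance = 1e-12)
  }
})
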