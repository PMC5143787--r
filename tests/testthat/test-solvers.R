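test_that("one sweep projects correctly: hand-computed and orthonormal cases", {
  expect_equal(kaczmarz_sweep(diag(2), c(1, 2), c(0, 0)), c(1, 2))
  # rows (1,0) then (1,1): successive projections land at (1.5, 0.5)
  B <- rbind(c(1, 0), c(1, 1))
  expect_equal(kaczmarz_sweep(B, c(1, 2), c(0, 0)), c(1.5, 0.5))
  # after the last row update the iterate satisfies that row exactly
  x <- kaczmarz_sweep(B, c(1, 2), c(0, 0))
  expect_equal(sum(B[2, ] * x), 2, tolerance = 1e-12)
})

test_that("compiled sweep agrees with a plain-R reference sweep", {
  set.seed(14)
  for (i in 1:5) {
    B <- matrix(rnorm(8 * 12), 8, 12)
    y <- rnorm(8)
    x0 <- rnorm(12)
    expect_equal(kaczmarz_sweep(B, y, x0), reference_sweep(B, y, x0),
                 tolerance = 1e-13)
  }
})

test_that("zero rows are skipped; an all-zero system is rejected", {
  B <- rbind(c(1, 0), c(0, 0))
  expect_equal(kaczmarz_sweep(B, c(2, 5), c(0, 0)), c(2, 0))
  expect_error(kaczmarz_sweep(matrix(0, 2, 3), c(1, 1), numeric(3)), "zero")
})

test_that("one preconditioned sweep solves a consistent full-row-rank system", {
  for (seed in 1:3) {
    A <- random_full_rank(20, 50, seed)
    x0 <- abs(rnorm(50))
    phi <- drop(A %*% x0)
    p <- apply_preconditioner(compute_preconditioner(A, 0), phi)
    x1 <- kaczmarz_sweep(p$B, p$y, numeric(50))
    expect_lt(sqrt(sum((p$B %*% x1 - p$y)^2)), 1e-8)
  }
})

test_that("classical Kaczmarz converges to the direct solution on square systems", {
  set.seed(8)
  A <- matrix(rnorm(64), 8, 8) + 4 * diag(8)
  x_star <- rnorm(8)
  phi <- drop(A %*% x_star)
  cfg <- solver_config(max_iterations = 5000, tolerance = 0,
                       apply_sparsity_constraint = FALSE)
  fit <- classical_kaczmarz(A, phi, cfg)
  expect_lt(sqrt(sum((fit$x - x_star)^2)), 1e-6)
})

test_that("classical Kaczmarz from zero converges to the minimum-norm solution", {
  set.seed(18)
  A <- matrix(rnorm(6 * 20), 6, 20)
  x0 <- rnorm(20)
  phi <- drop(A %*% x0)
  x_min <- drop(t(A) %*% solve(A %*% t(A), phi))  # pseudo-inverse solution
  cfg <- solver_config(max_iterations = 4000, tolerance = 0,
                       apply_sparsity_constraint = FALSE)
  fit <- classical_kaczmarz(A, phi, cfg)
  expect_lt(sqrt(sum((fit$x - x_min)^2)), 1e-6)
})

test_that("iteration accounting: K_iter = 1 does exactly one sweep + threshold", {
  A <- random_full_rank(5, 12, seed = 4)
  x0 <- abs(rnorm(12)); phi <- drop(A %*% x0)
  cfg <- solver_config(wanted_sparsity = 0.8, max_iterations = 1, tolerance = 0)
  fit <- scp_kaczmarz(A, phi, cfg)
  expect_equal(fit$iterations, 1L)
  expect_equal(nrow(tidy(fit)), 1L)
  p <- apply_preconditioner(compute_preconditioner(A, 0), phi)
  manual <- find_beta(kaczmarz_sweep(p$B, p$y, numeric(12)), 0.8)$x_thresholded
  expect_equal(fit$x, manual)
  expect_error(solver_config(wanted_sparsity = 0.8, max_iterations = 0),
               "max_iterations")
})

test_that("unconstrained, unpreconditioned scp_kaczmarz is bit-identical to the classical baseline", {
  A <- random_full_rank(10, 30, seed = 6)
  phi <- drop(A %*% abs(rnorm(30)))
  cfg <- solver_config(max_iterations = 25, tolerance = 0,
                       apply_sparsity_constraint = FALSE)
  a <- scp_kaczmarz(A, phi, cfg, precondition = FALSE)
  b <- classical_kaczmarz(A, phi, cfg)
  expect_identical(a$x, b$x)
  expect_identical(a$trace$update_norm, b$trace$update_norm)
})

test_that("SCP recovers a psi-sparse nonnegative truth on noiseless systems", {
  for (seed in c(2, 5)) {
    sys <- make_random_system(40, 80, "flat", n_nonzero = 6, seed = seed)
    psi <- hoyer_sparsity(sys$x_true)
    cfg <- solver_config(wanted_sparsity = psi, max_iterations = 200,
                         tolerance = 1e-10)
    fit <- scp_kaczmarz(sys$A, sys$phi_m, cfg, x_true = sys$x_true)
    expect_true(fit$converged)
    # support up to numerically-zero residue left by the final sweep
    expect_identical(which(fit$x > 1e-6 * max(fit$x)), which(sys$x_true > 0))
    expect_lt(relative_deviation(fit$x, sys$x_true), 0.05)
    expect_equal(hoyer_sparsity(fit$x), psi, tolerance = 0.05)
  }
})

test_that("every SCP iterate after thresholding is nonnegative with near-psi sparsity", {
  sys <- make_random_system(30, 60, "geometric", decay = 0.85, n_nonzero = 5, seed = 12)
  psi <- hoyer_sparsity(sys$x_true)
  cfg <- solver_config(wanted_sparsity = psi, max_iterations = 40, tolerance = 0)
  fit <- scp_kaczmarz(sys$A, sys$phi_m, cfg, x_true = sys$x_true)
  tr <- tidy(fit)
  expect_true(all(tr$sparsity >= 0 & tr$sparsity <= 1))
  expect_true(all(tr$update_norm >= 0))
  expect_true(all(fit$x >= 0))
  # each recorded sparsity is the best achievable for that iterate's candidates
  expect_true(all(abs(tr$sparsity - psi) <= 0.25))
})

test_that("preconditioning cuts sweeps-to-tolerance on decaying-spectrum systems", {
  # both solvers head to the same minimum-norm solution; compare how many
  # sweeps each needs to drive the residual below tolerance
  sys <- make_random_system(25, 50, "geometric", decay = 0.75, seed = 9)
  sweeps_to_resid <- function(B, y, tol, cap = 300) {
    x <- numeric(ncol(B))
    for (k in seq_len(cap)) {
      x <- kaczmarz_sweep(B, y, x)
      if (sqrt(sum((B %*% x - y)^2)) / sqrt(sum(y^2)) < tol) return(k)
    }
    Inf
  }
  p <- apply_preconditioner(compute_preconditioner(sys$A, 0), sys$phi_m)
  k_pre <- sweeps_to_resid(p$B, p$y, 1e-8)
  k_raw <- sweeps_to_resid(sys$A, sys$phi_m, 1e-8)
  expect_lt(k_pre, k_raw)
  expect_equal(k_pre, 1L)
})

test_that("solver shape and config errors are caught", {
  A <- random_full_rank(5, 10, seed = 1)
  cfg <- solver_config(wanted_sparsity = 0.9)
  expect_error(scp_kaczmarz(A, numeric(4), cfg), "shape error")
  expect_error(classical_kaczmarz(A, numeric(4),
               solver_config(apply_sparsity_constraint = FALSE)), "shape error")
  expect_error(solver_config(wanted_sparsity = 1.2), "wanted_sparsity")
  expect_error(solver_config(), "required")
})

test_that("noise-free two-target scenario: SCP localizes targets and outpaces classical Kaczmarz", {
  # mirrors the simulation design the method was built for: forward data
  # generated by the same diffusion model, no measurement noise
  scen <- make_scenario(two_target_config(noise_level = 0))
  psi <- wanted_sparsity_from_fraction(2 * pi / 400, length(scen$x_true))
  fit <- scp_kaczmarz(scen$A, scen$phi_m,
                      solver_config(wanted_sparsity = psi, max_iterations = 100,
                                    tolerance = 0),
                      x_true = scen$x_true)
  tr <- tidy(fit)
  expect_lt(min(tr$delta), 0.3)
  expect_gte(max(tr$dice_support, na.rm = TRUE), 0.8)
  expect_lt(localization_error(fit$x, scen$x_true, scen$grid), scen$grid$spacing)

  ck <- classical_kaczmarz(scen$A, scen$phi_m,
                           solver_config(max_iterations = 1500, tolerance = 0,
                                         apply_sparsity_constraint = FALSE),
                           x_true = scen$x_true)
  k_scp <- which(tr$delta <= 0.5)[1]
  k_classical <- which(tidy(ck)$delta <= 0.5)[1]
  expect_false(is.na(k_scp))
  expect_true(is.na(k_classical) || k_scp < k_classical)
})
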