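#' One sequential Kaczmarz sweep
#'
#' Applies, for `i = 1..M` in row order,
#' `x <- x + B_i' (y_i - B_i x) / (B_i B_i')`, i.e. one orthogonal projection
#' of the iterate onto each row's hyperplane in turn. One full sweep over all
#' rows is what the solvers count as one iteration. Rows with norm below
#' `1e-14` times the largest row norm are skipped.
#'
#' @param B System matrix (`M x N`).
#' @param y Right-hand side, length `M`.
#' @param x Current iterate, length `N`.
#' @return The updated iterate.
#' @export
kaczmarz_sweep <- function(B, y, x) {
  B <- as_forward_matrix(B)
  if (length(y) != nrow(B) || length(x) != ncol(B)) {
    stop(sprintf("shape error: B is %d x %d but length(y) = %d, length(x) = %d",
                 nrow(B), ncol(B), length(y), length(x)))
  }
  drop(kaczmarz_sweep_t(t(B), as.numeric(y), as.numeric(x)))
}

#' Solver configuration
#'
#' @param wanted_sparsity Wanted Hoyer sparsity `psi` in `(0, 1]` that each
#'   iterate is thresholded toward. Required when the sparsity constraint is
#'   on; see [wanted_sparsity_from_fraction()] for a principled choice.
#' @param max_iterations Iteration cap `K_iter >= 1`; one iteration is one
#'   full sweep (plus one thresholding when the constraint is on).
#' @param tolerance Stop once the update norm `||x_k - x_(k-1)||_2` drops
#'   below this; `>= 0`. Default `1e-6`.
#' @param initial_x Initial iterate; default the zero vector.
#' @param apply_sparsity_constraint Logical; `FALSE` gives the unconstrained
#'   Kaczmarz iteration.
#' @return An object of class `scpk_config`.
#' @export
solver_config <- function(wanted_sparsity = NULL, max_iterations = 100L,
                          tolerance = 1e-6, initial_x = NULL,
                          apply_sparsity_constraint = TRUE) {
  if (!is.null(wanted_sparsity) &&
      (!is.numeric(wanted_sparsity) || wanted_sparsity <= 0 || wanted_sparsity > 1)) {
    stop("invalid parameter: wanted_sparsity must be in (0, 1]")
  }
  if (isTRUE(apply_sparsity_constraint) && is.null(wanted_sparsity)) {
    stop("wanted_sparsity is required when the sparsity constraint is on")
  }
  max_iterations <- as.integer(max_iterations)
  if (is.na(max_iterations) || max_iterations < 1L) {
    stop("invalid parameter: max_iterations must be >= 1")
  }
  if (!is.numeric(tolerance) || tolerance < 0) {
    stop("invalid parameter: tolerance must be >= 0")
  }
  structure(list(wanted_sparsity = wanted_sparsity,
                 max_iterations = max_iterations,
                 tolerance = tolerance,
                 initial_x = initial_x,
                 apply_sparsity_constraint = isTRUE(apply_sparsity_constraint)),
            class = "scpk_config")
}

# Shared iteration loop for both solvers. B/y is the (possibly
# preconditioned) system; the trace records the paper-style diagnostics.
run_kaczmarz_loop <- function(B, y, config, x_true = NULL, constrain = FALSE,
                              grid = NULL) {
  N <- ncol(B)
  x <- config$initial_x
  if (is.null(x)) x <- numeric(N)
  if (length(x) != N) stop("shape error: initial_x has the wrong length")
  Bt <- t(B)

  K <- config$max_iterations
  trace <- list(k = integer(K), delta = rep(NA_real_, K), dice = rep(NA_real_, K),
                dice_support = rep(NA_real_, K), sparsity = rep(NA_real_, K),
                update_norm = numeric(K), beta = rep(NA_real_, K))
  converged <- FALSE
  n_done <- 0L
  for (k in seq_len(K)) {
    x_prev <- x
    x <- drop(kaczmarz_sweep_t(Bt, y, x))
    beta_k <- NA_real_
    if (constrain) {
      fb <- find_beta(x, config$wanted_sparsity)
      x <- fb$x_thresholded
      beta_k <- fb$beta
    }
    n_done <- k
    trace$k[k] <- k
    trace$beta[k] <- beta_k
    trace$update_norm[k] <- sqrt(sum((x - x_prev)^2))
    if (any(x != 0)) trace$sparsity[k] <- hoyer_sparsity(x)
    if (!is.null(x_true)) {
      trace$delta[k] <- relative_deviation(x, x_true)
      if (any(x != 0)) {
        trace$dice[k] <- dice_coefficient(x, x_true)
        trace$dice_support[k] <- dice_support(x, x_true)
      }
    }
    if (trace$update_norm[k] < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  trace <- tibble::as_tibble(lapply(trace, function(v) v[seq_len(n_done)]))
  list(x = x, trace = trace, converged = converged, iterations = n_done)
}

new_scpk_fit <- function(res, method, config, loading = NA_real_, system = NULL) {
  structure(list(x = res$x, trace = res$trace, converged = res$converged,
                 iterations = res$iterations, method = method, config = config,
                 loading = loading,
                 rank = if (is.null(system)) NA_integer_ else system$rank,
                 sigma_max = if (is.null(system)) NA_real_ else system$sigma_max,
                 sigma_min = if (is.null(system)) NA_real_ else system$sigma_min),
            class = "scpk_fit")
}

#' Sparsity-constrained preconditioned Kaczmarz reconstruction
#'
#' The full solver: (1) compute the row-orthogonalizing preconditioner
#' `W` from the SVD of `A` (with optional diagonal loading); (2) form
#' `B = W A` and `y = W phi_m`; (3) repeat one sequential Kaczmarz sweep
#' followed by thresholding the iterate to the wanted sparsity `psi`, until
#' the iteration cap is reached or the update norm drops below the tolerance.
#' With `precondition = FALSE` and the sparsity constraint off this reduces
#' exactly to [classical_kaczmarz()].
#'
#' @param A Forward matrix (`M x N` matrix or `fmt_sensitivity`).
#' @param phi_m Measurement vector, length `M`.
#' @param config A [solver_config()].
#' @param loading Diagonal loading `lambda` passed to
#'   [compute_preconditioner()] (`0`, positive value, or `"auto"`).
#' @param truncate Relative spectral cutoff passed to
#'   [compute_preconditioner()]; the regularization knob for noisy data.
#' @param x_true Optional ground-truth yield; when supplied the trace records
#'   relative deviation and Dice per iteration.
#' @param precondition Logical; `FALSE` skips the preconditioner entirely
#'   (`B = A`, `y = phi_m`).
#' @return An object of class `scpk_fit`: the recovered `x`, a per-iteration
#'   `trace` tibble (`k`, `delta`, `dice`, `dice_support`, `sparsity`,
#'   `update_norm`, `beta`), convergence flags and preconditioner summary.
#'   Use [tidy()], [glance()] and [autoplot()] on it.
#' @seealso [classical_kaczmarz()], [compute_preconditioner()], [find_beta()]
#' @export
scp_kaczmarz <- function(A, phi_m, config, loading = 0, truncate = 0,
                         x_true = NULL, precondition = TRUE) {
  stopifnot(inherits(config, "scpk_config"))
  grid <- if (inherits(A, "fmt_sensitivity")) A$grid else NULL
  A <- as_forward_matrix(A)
  if (length(phi_m) != nrow(A)) {
    stop(sprintf("shape error: phi_m has length %d but A has %d rows",
                 length(phi_m), nrow(A)))
  }
  system <- NULL
  if (precondition) {
    system <- compute_preconditioner(A, loading, truncate)
    system <- apply_preconditioner(system, phi_m)
    B <- system$B; y <- system$y
    lambda <- system$loading
  } else {
    B <- A; y <- as.numeric(phi_m); lambda <- 0
  }
  res <- run_kaczmarz_loop(B, y, config, x_true,
                           constrain = config$apply_sparsity_constraint,
                           grid = grid)
  new_scpk_fit(res, "scp_kaczmarz", config, lambda, system)
}

#' Classical Kaczmarz (ART) baseline
#'
#' Iterates sequential Kaczmarz sweeps on the raw system `A x = phi_m` with
#' no preconditioning and no thresholding, under the same stopping rules and
#' trace as [scp_kaczmarz()]. From a zero start on a consistent system it
#' converges to the minimum-norm solution.
#'
#' @inheritParams scp_kaczmarz
#' @return An object of class `scpk_fit`.
#' @export
classical_kaczmarz <- function(A, phi_m, config, x_true = NULL) {
  stopifnot(inherits(config, "scpk_config"))
  grid <- if (inherits(A, "fmt_sensitivity")) A$grid else NULL
  A <- as_forward_matrix(A)
  if (length(phi_m) != nrow(A)) {
    stop(sprintf("shape error: phi_m has length %d but A has %d rows",
                 length(phi_m), nrow(A)))
  }
  res <- run_kaczmarz_loop(A, as.numeric(phi_m), config, x_true,
                           constrain = FALSE, grid = grid)
  new_scpk_fit(res, "kaczmarz", config)
}

#' @export
print.scpk_fit <- function(x, ...) {
  cat(sprintf("<scpk_fit> method: %s, %d iteration(s), %s\n", x$method,
              x$iterations,
              if (x$converged) "converged (update norm below tolerance)"
              else "stopped at iteration cap"))
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final sparsity %.4f, update norm %.3e",
              last$sparsity, last$update_norm))
  if (!is.na(last$delta)) cat(sprintf(", relative deviation %.4f", last$delta))
  cat("\n")
  invisible(x)
}

#' Broom-style accessors for Kaczmarz fits
#'
#' `tidy()` returns the per-iteration trace as a tibble; `glance()` a
#' one-row summary of the fit.
#'
#' @param x An `scpk_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.scpk_fit <- function(x, ...) x$trace

#' @rdname tidy.scpk_fit
#' @export
glance.scpk_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(method = x$method, iterations = x$iterations,
                 converged = x$converged, loading = x$loading,
                 delta = last$delta, dice = last$dice,
                 dice_support = last$dice_support,
                 sparsity = last$sparsity, update_norm = last$update_norm)
}
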