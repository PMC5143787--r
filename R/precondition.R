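#' Row-orthogonalizing preconditioner from the SVD of A
#'
#' Given the SVD `A = U S V'`, the left preconditioner
#' `W = (S S' + lambda I)^(-1/2) U'` makes the rows of `B = W A` mutually
#' orthogonal: with `lambda = 0` and full row rank, `B B' = I`. Diagonal
#' loading `lambda > 0` damps the amplification of directions with small
#' singular values, which matters for noisy, ill-conditioned systems. With
#' `lambda = 0`, singular values below the numerical-rank tolerance
#' `max(M, N) * eps * sigma_max` are treated as exactly zero and their
#' reciprocals set to zero (pseudo-inverse convention), so rank-deficient
#' input yields a projection rather than NaNs.
#'
#' @param A An `M x N` forward matrix (or `fmt_sensitivity`), nonzero.
#' @param loading Diagonal loading constant `lambda >= 0`. The default `0`
#'   applies the pure pseudo-inverse convention; `"auto"` uses
#'   `1e-6 * sigma_max^2`.
#' @param truncate Relative spectral cutoff in `[0, 1)`: singular values
#'   below `truncate * sigma_max` are zeroed under the same pseudo-inverse
#'   convention as the rank tolerance (their preconditioned rows vanish and
#'   the solver skips them). The default `0` keeps the machine-rank rule
#'   only. Because every retained row of `B` is enforced exactly by the
#'   Kaczmarz projections, noise in directions with small singular values is
#'   amplified by `1/sigma`; setting `truncate` near the measurement
#'   noise-to-signal ratio is the discrepancy-principle choice for noisy
#'   data.
#' @return An object of class `fmt_precond` with fields `W` (`M x M`), `B`
#'   (`= W A`), `y` (`NULL` until [apply_preconditioner()] attaches it),
#'   `loading`, `row_norms`, `rank`, `sigma_max`, `sigma_min` (smallest
#'   singular value above the rank tolerance).
#' @export
compute_preconditioner <- function(A, loading = 0, truncate = 0) {
  A <- as_forward_matrix(A)
  if (all(A == 0)) stop("degenerate input: A is all zero")
  M <- nrow(A); N <- ncol(A)

  sv <- svd(A, nu = M, nv = 0)
  d <- sv$d                      # length min(M, N)
  sigma_max <- d[1]
  if (identical(loading, "auto")) loading <- 1e-6 * sigma_max^2
  if (!is.numeric(loading) || loading < 0) stop("loading must be >= 0 or \"auto\"")
  if (!is.numeric(truncate) || truncate < 0 || truncate >= 1) {
    stop("truncate must be in [0, 1)")
  }

  tol <- max(max(M, N) * .Machine$double.eps, truncate) * sigma_max
  rank <- sum(d > tol)
  s2 <- numeric(M)               # diagonal of S S', zero-padded when M > N
  s2[seq_along(d)] <- d^2
  keep <- sqrt(s2) > tol
  f <- if (loading > 0) ifelse(keep, 1 / sqrt(s2 + loading), 0)
       else ifelse(keep, 1 / sqrt(s2), 0)

  W <- f * t(sv$u)               # (S S' + lambda I)^(-1/2) U'
  B <- W %*% A
  structure(
    list(W = W, B = B, y = NULL, loading = loading,
         row_norms = sqrt(rowSums(B^2)),
         rank = rank, sigma_max = sigma_max,
         sigma_min = if (rank > 0) d[rank] else 0),
    class = "fmt_precond"
  )
}

#' Attach preconditioned measurements to a preconditioned system
#'
#' Computes `y = W phi_m`, the measurement vector of the preconditioned
#' system `B x = y`.
#'
#' @param system An `fmt_precond` from [compute_preconditioner()].
#' @param phi_m Length-`M` measurement vector.
#' @return The system with field `y` filled in.
#' @export
apply_preconditioner <- function(system, phi_m) {
  stopifnot(inherits(system, "fmt_precond"))
  if (length(phi_m) != nrow(system$W)) {
    stop(sprintf("shape error: phi_m has length %d but W is %d x %d",
                 length(phi_m), nrow(system$W), ncol(system$W)))
  }
  system$y <- drop(system$W %*% phi_m)
  system
}

#' @export
print.fmt_precond <- function(x, ...) {
  cat(sprintf("<fmt_precond> B: %d x %d, rank %d, sigma in [%.3e, %.3e], lambda = %.3e\n",
              nrow(x$B), ncol(x$B), x$rank, x$sigma_min, x$sigma_max, x$loading))
  invisible(x)
}

#' Maximum absolute cosine similarity between distinct rows
#'
#' The quantity the preconditioner drives toward zero: rows that are nearly
#' parallel make successive Kaczmarz projections nearly redundant and slow
#' convergence. Zero-norm rows are skipped.
#'
#' @param Mtx A matrix with at least two nonzero rows.
#' @return Scalar in `[0, 1]`.
#' @export
row_coherence <- function(Mtx) {
  Mtx <- as_forward_matrix(Mtx)
  norms <- sqrt(rowSums(Mtx^2))
  keep <- norms > 0
  if (sum(keep) < 2L) stop("degenerate input: need at least 2 nonzero rows")
  R <- Mtx[keep, , drop = FALSE] / norms[keep]
  G <- abs(R %*% t(R))
  diag(G) <- 0
  min(max(G), 1)
}
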