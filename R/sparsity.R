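#' Hoyer sparseness measure
#'
#' `(sqrt(N) - ||x||_1 / ||x||_2) / (sqrt(N) - 1)`, ranging from 0 when all
#' entries are equal in magnitude to 1 when exactly one entry is nonzero.
#' This is the sparseness value the solver steers each iterate toward.
#'
#' @param x Numeric vector with at least two entries, not all zero.
#' @return Scalar in `[0, 1]`.
#' @examples
#' hoyer_sparsity(c(1, rep(0, 299)))   # 1
#' hoyer_sparsity(rep(1, 300))         # 0
#' @export
hoyer_sparsity <- function(x) {
  N <- length(x)
  if (N < 2L) stop("invalid input: x must have at least 2 entries")
  l2 <- sqrt(sum(x^2))
  if (l2 == 0) stop("undefined sparsity: x is all zero")
  (sqrt(N) - sum(abs(x)) / l2) / (sqrt(N) - 1)
}

#' Hard-threshold a vector relative to its maximum
#'
#' Keeps `x_n` where `x_n >= beta * max(x)` and zeroes the rest — the signed
#' comparison, not a magnitude one. When `max(x) > 0`, any `beta > 0` (and
#' also `beta = 0`, whose threshold is exactly 0) zeroes all negative
#' entries, so thresholded iterates are nonnegative.
#'
#' @param x Nonempty numeric vector.
#' @param beta Threshold fraction in `[0, 1]`.
#' @return Vector of the same length with sub-threshold entries set to 0.
#' @export
sparsity_threshold <- function(x, beta) {
  if (length(x) == 0L) stop("invalid input: x is empty")
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta < 0 || beta > 1) {
    stop("invalid parameter: beta must be a scalar in [0, 1]")
  }
  x[x < beta * max(x)] <- 0
  x
}

#' Find the threshold matching a wanted sparsity
#'
#' Searches for the `beta` whose thresholded vector has Hoyer sparseness
#' closest to the wanted value `psi`. Because the threshold rule can only
#' retain a top set of the positive entries, the search space is the discrete
#' family of supports induced by the sorted distinct positive values of `x`
#' (each realizable by `beta = v / max(x)`); the candidate minimizing
#' `|sparsity - psi|` is selected exactly, ties broken toward the sparser
#' result (larger `beta`).
#'
#' @param x Numeric vector, not all zero.
#' @param psi Wanted sparsity in `(0, 1]`.
#' @return List with `beta`, `x_thresholded` (`= sparsity_threshold(x, beta)`),
#'   `sparsity` (achieved value), `objective` (`|sparsity - psi|`), and
#'   `degenerate` (`TRUE` when `x` has no positive entry, in which case a
#'   zero vector is returned with a warning).
#' @export
find_beta <- function(x, psi) {
  if (all(x == 0)) stop("degenerate input: x is all zero")
  if (!is.numeric(psi) || length(psi) != 1L || psi <= 0 || psi > 1) {
    stop("invalid parameter: psi must be in (0, 1]")
  }
  pos <- x[x > 0]
  if (length(pos) == 0L) {
    warning("no positive entry to retain; returning the zero vector")
    return(list(beta = NA_real_, x_thresholded = numeric(length(x)),
                sparsity = NA_real_, objective = NA_real_, degenerate = TRUE))
  }
  N <- length(x)
  vs <- sort(pos, decreasing = TRUE)
  l1 <- cumsum(vs)
  l2 <- sqrt(cumsum(vs^2))
  s_m <- (sqrt(N) - l1 / l2) / (sqrt(N) - 1)
  # realizable supports: value boundaries (strictly decreasing steps) + full set
  cand <- which(c(vs[-length(vs)] > vs[-1], TRUE))
  obj <- abs(s_m[cand] - psi)
  m <- cand[which.min(obj)]       # which.min takes the first = sparser on ties
  # beta realizing the chosen support; nudged down so that beta * max(x)
  # does not round above the retained value and drop it
  beta <- vs[m] / vs[1]
  while (beta * vs[1] > vs[m]) beta <- beta * (1 - .Machine$double.eps)
  list(beta = beta, x_thresholded = sparsity_threshold(x, beta),
       sparsity = s_m[m], objective = abs(s_m[m] - psi), degenerate = FALSE)
}

#' Wanted sparsity from an estimated target-volume fraction
#'
#' In practice the true yield distribution is unknown, but the fraction `f`
#' of the imaging domain occupied by fluorescent target can be estimated.
#' Assuming the target is uniformly distributed over `round(f * N)` of the
#' `N` nodes (clamped to at least 1), the corresponding Hoyer sparseness is
#' `(sqrt(N) - sqrt(round(f * N))) / (sqrt(N) - 1)`, which serves as the
#' wanted sparsity `psi`.
#'
#' @param fraction Target-volume fraction `f` in `(0, 1]`.
#' @param N Number of unknowns (grid nodes), at least 2.
#' @return Wanted sparsity `psi` in `[0, 1]`.
#' @export
wanted_sparsity_from_fraction <- function(fraction, N) {
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 || fraction > 1) {
    stop("invalid parameter: fraction must be in (0, 1]")
  }
  if (N < 2L) stop("invalid parameter: N must be >= 2")
  k <- max(1, round(fraction * N))
  (sqrt(N) - sqrt(k)) / (sqrt(N) - 1)
}
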