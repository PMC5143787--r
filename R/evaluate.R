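#' Relative deviation between a reconstruction and the truth
#'
#' `delta = ||x_r - x_t||_2 / ||x_t||_2`, the primary accuracy metric.
#'
#' @param x_r Reconstructed yield vector.
#' @param x_t Ground-truth yield vector, nonzero.
#' @return Nonnegative scalar.
#' @export
relative_deviation <- function(x_r, x_t) {
  if (length(x_r) != length(x_t)) stop("shape error: vectors differ in length")
  nt <- sqrt(sum(x_t^2))
  if (nt == 0) stop("undefined metric: ground truth is all zero")
  sqrt(sum((x_r - x_t)^2)) / nt
}

#' Dice coefficient (intensity form, as conventionally reported in FMT)
#'
#' `D = 2 ||x_r . x_t||_2 / (||x_r||_2^2 ||x_t||_2^2)` with `.` the Hadamard
#' product. Note this intensity-weighted form is not bounded by 1 (a pair of
#' matching unit spikes gives 2) and scales inversely with the amplitude of
#' either argument; use [dice_support()] for a bounded overlap score.
#'
#' @param x_r,x_t Vectors of equal length, both nonzero.
#' @return Nonnegative scalar (may exceed 1).
#' @export
dice_coefficient <- function(x_r, x_t) {
  if (length(x_r) != length(x_t)) stop("shape error: vectors differ in length")
  nr2 <- sum(x_r^2); nt2 <- sum(x_t^2)
  if (nr2 == 0 || nt2 == 0) stop("undefined metric: zero vector input")
  2 * sqrt(sum((x_r * x_t)^2)) / (nr2 * nt2)
}

#' Support-overlap Dice coefficient
#'
#' The conventional bounded Dice on supports:
#' `2 |S_r intersect S_t| / (|S_r| + |S_t|)`, where a node belongs to a
#' support when its value exceeds `threshold` times the vector's maximum
#' (strictly positive entries when `threshold = 0`). The default cut of 0.1
#' is the usual 10%-of-maximum isocontour used to segment reconstructed
#' targets; a strict zero cut is oversensitive to numerically tiny entries
#' that the sparsity-matched thresholding may retain (the Hoyer measure is
#' nearly blind to negligible values, so the matched support can carry such
#' dust without moving the sparsity).
#'
#' @param x_r,x_t Vectors of equal length.
#' @param threshold Support cut as a fraction of each vector's maximum,
#'   in `[0, 1)`. Default 0.1.
#' @return Scalar in `[0, 1]`.
#' @export
dice_support <- function(x_r, x_t, threshold = 0.1) {
  if (length(x_r) != length(x_t)) stop("shape error: vectors differ in length")
  if (threshold < 0 || threshold >= 1) stop("invalid parameter: threshold in [0, 1)")
  sup <- function(v) if (max(v) <= 0) rep(FALSE, length(v)) else v > threshold * max(v)
  sr <- sup(x_r); st <- sup(x_t)
  denom <- sum(sr) + sum(st)
  if (denom == 0) stop("undefined metric: both supports are empty")
  2 * sum(sr & st) / denom
}

#' Localization error between reconstructed and true targets
#'
#' Euclidean distance (mm) between the intensity-weighted centers of mass of
#' the two yield vectors in physical grid coordinates. Negative entries are
#' clipped to zero before weighting.
#'
#' @param x_r,x_t Yield vectors over the grid nodes, each with at least one
#'   positive entry.
#' @param grid The [imaging_grid()] the vectors live on.
#' @return Distance in mm.
#' @export
localization_error <- function(x_r, x_t, grid) {
  stopifnot(inherits(grid, "fmt_grid"))
  if (length(x_r) != grid_n_nodes(grid) || length(x_t) != grid_n_nodes(grid)) {
    stop("shape error: vector length does not match the grid")
  }
  co <- grid_coordinates(grid)
  com <- function(v) {
    w <- pmax(v, 0)
    if (sum(w) == 0) stop("undefined metric: no positive entry")
    colSums(co * w) / sum(w)
  }
  sqrt(sum((com(x_r) - com(x_t))^2))
}

#' One-row evaluation report for a reconstruction
#'
#' @param x_r Reconstructed yield vector.
#' @param x_t Ground-truth yield vector.
#' @param grid Optional [imaging_grid()]; when given, the localization error
#'   is included.
#' @return A one-row tibble with columns `delta`, `dice`, `dice_support`,
#'   `sparsity`, and `localization_error_mm` (`NA` without a grid).
#' @export
evaluate_reconstruction <- function(x_r, x_t, grid = NULL) {
  tibble::tibble(
    delta = relative_deviation(x_r, x_t),
    dice = dice_coefficient(x_r, x_t),
    dice_support = dice_support(x_r, x_t),
    sparsity = hoyer_sparsity(x_r),
    localization_error_mm = if (is.null(grid)) NA_real_
                            else localization_error(x_r, x_t, grid)
  )
}
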