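#' Diffusion coefficient from absorption and reduced scattering
#'
#' In the diffusion approximation of photon transport the diffusion
#' coefficient is `D = 1 / (3 * (mu_a + mu_s_prime))`, in mm, where `mu_a` is
#' the absorption coefficient and `mu_s_prime = (1 - g) * mu_s` the reduced
#' scattering coefficient (both in 1/mm).
#'
#' @param mu_a Absorption coefficient (1/mm), strictly positive.
#' @param mu_s_prime Reduced scattering coefficient (1/mm), strictly positive.
#' @return Diffusion coefficient in mm.
#' @examples
#' diffusion_coefficient(0.0052, 1.08) # murine muscle at excitation
#' @export
diffusion_coefficient <- function(mu_a, mu_s_prime) {
  if (!is.numeric(mu_a) || !is.numeric(mu_s_prime) ||
      any(mu_a <= 0) || any(mu_s_prime <= 0)) {
    stop("invalid parameter: mu_a and mu_s_prime must be strictly positive")
  }
  1 / (3 * (mu_a + mu_s_prime))
}

#' Optical properties of a homogeneous imaging domain
#'
#' Bundles the four coefficients governing light transport at the excitation
#' (`x`) and emission (`m`) wavelengths and derives the two diffusion
#' coefficients. Reduced scattering is stored directly, so the anisotropy
#' factor is already folded in.
#'
#' @param mu_ax,mu_am Absorption coefficients at excitation / emission (1/mm).
#' @param mu_sx_prime,mu_sm_prime Reduced scattering coefficients at
#'   excitation / emission (1/mm).
#' @return An object of class `fmt_optics` with fields `mu_ax`, `mu_am`,
#'   `mu_sx_prime`, `mu_sm_prime`, `D_x`, `D_m`.
#' @examples
#' muscle_optics() # Cy5.5-band murine muscle values
#' @export
optical_properties <- function(mu_ax, mu_sx_prime, mu_am, mu_sm_prime) {
  props <- list(
    mu_ax = mu_ax, mu_sx_prime = mu_sx_prime,
    mu_am = mu_am, mu_sm_prime = mu_sm_prime,
    D_x = diffusion_coefficient(mu_ax, mu_sx_prime),
    D_m = diffusion_coefficient(mu_am, mu_sm_prime)
  )
  structure(props, class = "fmt_optics")
}

#' @rdname optical_properties
#' @export
muscle_optics <- function() optical_properties(0.0052, 1.08, 0.0068, 1.03)

#' Rectangular node-centered imaging grid
#'
#' Defines the 2D discretization of the imaging domain: `nx * ny` nodes at
#' pitch `spacing` (mm), enumerated row-major (x index fastest). Node (1,1)
#' sits at `origin`; the physical domain is the bounding box of the nodes.
#' `robin` is the boundary-mismatch factor kappa in the Robin condition
#' `Phi + 2 * kappa * D * dPhi/dn = 0` (kappa = 1 is index-matched).
#'
#' @param nx,ny Node counts per axis, each at least 3.
#' @param spacing Node pitch in mm, positive.
#' @param origin Physical coordinates (mm) of node (1,1). Length-2 numeric.
#' @param robin Robin boundary-mismatch factor, positive. Default 1.
#' @return An object of class `fmt_grid`.
#' @export
imaging_grid <- function(nx, ny, spacing, origin = c(0, 0), robin = 1) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3L || ny < 3L) stop("invalid grid: nx and ny must be >= 3")
  if (!is.numeric(spacing) || spacing <= 0) stop("invalid grid: spacing must be > 0")
  if (length(origin) != 2L) stop("invalid grid: origin must have length 2")
  if (!is.numeric(robin) || robin <= 0) stop("invalid grid: robin factor must be > 0")
  structure(
    list(nx = nx, ny = ny, spacing = as.numeric(spacing),
         origin = as.numeric(origin), robin = as.numeric(robin)),
    class = "fmt_grid"
  )
}

#' @export
print.fmt_grid <- function(x, ...) {
  ext <- grid_extent(x)
  cat(sprintf("<fmt_grid> %d x %d nodes, pitch %.4g mm, domain [%.4g, %.4g] x [%.4g, %.4g] mm\n",
              x$nx, x$ny, x$spacing, ext[1], ext[2], ext[3], ext[4]))
  invisible(x)
}

grid_n_nodes <- function(grid) grid$nx * grid$ny

# xmin, xmax, ymin, ymax of the physical domain (mm)
grid_extent <- function(grid) {
  c(grid$origin[1], grid$origin[1] + (grid$nx - 1L) * grid$spacing,
    grid$origin[2], grid$origin[2] + (grid$ny - 1L) * grid$spacing)
}

#' Node coordinates and boundary structure of a grid
#'
#' `grid_coordinates()` returns an `N x 2` matrix of physical node positions
#' (mm) in row-major node order; `boundary_nodes()` the indices of nodes on
#' the domain boundary; `nearest_node()` the index of the node closest to a
#' physical position.
#'
#' @param grid An [imaging_grid()].
#' @return See individual descriptions.
#' @export
grid_coordinates <- function(grid) {
  ix <- rep(seq_len(grid$nx), times = grid$ny)
  iy <- rep(seq_len(grid$ny), each = grid$nx)
  cbind(x = grid$origin[1] + (ix - 1L) * grid$spacing,
        y = grid$origin[2] + (iy - 1L) * grid$spacing)
}

#' @rdname grid_coordinates
#' @export
boundary_nodes <- function(grid) {
  ix <- rep(seq_len(grid$nx), times = grid$ny)
  iy <- rep(seq_len(grid$ny), each = grid$nx)
  which(ix == 1L | ix == grid$nx | iy == 1L | iy == grid$ny)
}

#' @rdname grid_coordinates
#' @param position Length-2 numeric physical position (mm).
#' @export
nearest_node <- function(grid, position) {
  if (length(position) != 2L) stop("position must have length 2")
  ext <- grid_extent(grid)
  if (position[1] < ext[1] - grid$spacing / 2 || position[1] > ext[2] + grid$spacing / 2 ||
      position[2] < ext[3] - grid$spacing / 2 || position[2] > ext[4] + grid$spacing / 2) {
    stop("position lies outside the imaging domain")
  }
  ix <- min(max(1L, as.integer(round((position[1] - grid$origin[1]) / grid$spacing)) + 1L), grid$nx)
  iy <- min(max(1L, as.integer(round((position[2] - grid$origin[2]) / grid$spacing)) + 1L), grid$ny)
  (iy - 1L) * grid$nx + ix
}

#' Point source specification
#'
#' @param position Length-2 physical coordinates (mm), inside the domain.
#' @param amplitude Source strength Theta (arbitrary units), positive.
#' @return An object of class `fmt_source`.
#' @export
source_spec <- function(position, amplitude = 1) {
  if (length(position) != 2L) stop("source position must have length 2")
  if (!is.numeric(amplitude) || amplitude <= 0) stop("source amplitude must be > 0")
  structure(list(position = as.numeric(position), amplitude = as.numeric(amplitude)),
            class = "fmt_source")
}

# Symmetric finite-volume discretization of -div(D grad Phi) + mu_a Phi on the
# grid, integrated over unit-pitch cells: interior faces contribute D on the
# off-diagonal graph Laplacian, each exposed boundary face adds the Robin flux
# h / (2 kappa) to the diagonal, and absorption adds mu_a h^2. The result is a
# symmetric positive-definite M-matrix, so fields driven by nonnegative
# sources are strictly positive.
diffusion_operator <- function(grid, mu_a, D) {
  if (mu_a <= 0 || D <= 0) stop("invalid parameter: mu_a and D must be > 0")
  nx <- grid$nx; ny <- grid$ny; h <- grid$spacing
  N <- nx * ny
  idx <- matrix(seq_len(N), nrow = nx, ncol = ny)

  # horizontal and vertical adjacencies
  i_h <- as.vector(idx[-nx, , drop = FALSE]); j_h <- as.vector(idx[-1, , drop = FALSE])
  i_v <- as.vector(idx[, -ny, drop = FALSE]); j_v <- as.vector(idx[, -1, drop = FALSE])
  ii <- c(i_h, i_v); jj <- c(j_h, j_v)

  deg <- tabulate(c(ii, jj), nbins = N)
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  n_exposed <- (ix == 1L) + (ix == nx) + (iy == 1L) + (iy == ny)

  diag_val <- D * deg + (h / (2 * grid$robin)) * n_exposed + mu_a * h^2
  Matrix::sparseMatrix(
    i = c(seq_len(N), ii, jj),
    j = c(seq_len(N), jj, ii),
    x = c(diag_val, rep(-D, 2L * length(ii))),
    dims = c(N, N), symmetric = FALSE
  )
}

new_field <- function(values, grid, wavelength) {
  structure(list(values = as.numeric(values), grid = grid, wavelength = wavelength),
            class = "fmt_field")
}

#' @export
print.fmt_field <- function(x, ...) {
  cat(sprintf("<fmt_field> %s wavelength, %d nodes, range [%.3e, %.3e]\n",
              x$wavelength, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Solve the diffusion equation for a point source
#'
#' Solves `-div(D grad Phi) + mu_a Phi = Theta * delta(r - r_s)` on the grid
#' with the Robin boundary condition `Phi + 2 kappa D dPhi/dn = 0`, using a
#' symmetric 5-point finite-volume discretization. The point source is
#' deposited on its nearest node as a density of `Theta / spacing^2`, i.e. a
#' unit-cell integrated load of `Theta`.
#'
#' @param grid An [imaging_grid()].
#' @param mu_a Absorption coefficient (1/mm) at the field's wavelength.
#' @param D Diffusion coefficient (mm) at the field's wavelength.
#' @param source A [source_spec()].
#' @param wavelength Tag stored on the result, `"excitation"` or `"emission"`.
#' @return An `fmt_field` whose `values` hold the photon density at every node.
#' @export
solve_diffusion_field <- function(grid, mu_a, D, source,
                                  wavelength = c("excitation", "emission")) {
  wavelength <- match.arg(wavelength)
  if (!inherits(source, "fmt_source")) source <- source_spec(source)
  M <- diffusion_operator(grid, mu_a, D)
  b <- numeric(grid_n_nodes(grid))
  b[nearest_node(grid, source$position)] <- source$amplitude
  phi <- tryCatch(as.numeric(Matrix::solve(M, b)),
                  error = function(e) stop("numerical error: singular diffusion operator"))
  if (anyNA(phi) || any(!is.finite(phi))) stop("numerical error: diffusion solve failed")
  new_field(phi, grid, wavelength)
}

#' Assemble the FMT sensitivity (forward) matrix
#'
#' Builds the `M x N` Born-type forward matrix `A` mapping node-wise
#' fluorescent yield to boundary measurements: row `(s, d)` has entries
#' `A[(s,d), j] = Phi_x^(s)(r_j) * G_m^(d)(r_j) * spacing^2`, where
#' `Phi_x^(s)` is the excitation field of source `s` and `G_m^(d)` is the
#' emission-wavelength adjoint field driven by a unit load at detector `d`.
#' Rows are ordered source-major with detectors in input order.
#'
#' @param grid An [imaging_grid()].
#' @param props An [optical_properties()] object.
#' @param sources List of [source_spec()] objects (or length-2 positions).
#' @param detectors List (or `n x 2` matrix) of physical detector positions in
#'   mm; each must coincide with a boundary node.
#' @return An object of class `fmt_sensitivity` with fields `A` (dense
#'   matrix), `row_index` (tibble of source/detector per row), `src_nodes`,
#'   `det_nodes`, `grid`, `props`.
#' @export
assemble_sensitivity_matrix <- function(grid, props, sources, detectors) {
  stopifnot(inherits(grid, "fmt_grid"), inherits(props, "fmt_optics"))
  if (inherits(sources, "fmt_source")) sources <- list(sources)
  sources <- lapply(sources, function(s) if (inherits(s, "fmt_source")) s else source_spec(s))
  if (is.matrix(detectors)) detectors <- asplit(detectors, 1L)
  if (length(sources) < 1L || length(detectors) < 1L) {
    stop("need at least one source and one detector")
  }

  N <- grid_n_nodes(grid)
  h <- grid$spacing
  bnodes <- boundary_nodes(grid)

  src_nodes <- vapply(sources, function(s) nearest_node(grid, s$position), integer(1))
  det_nodes <- vapply(detectors, function(d) {
    nd <- nearest_node(grid, d)
    co <- grid_coordinates(grid)[nd, ]
    if (max(abs(co - as.numeric(d))) > h / 2 + 1e-9) stop("layout error: detector off-grid")
    nd
  }, integer(1))
  if (!all(det_nodes %in% bnodes)) stop("layout error: detector not on a boundary node")

  Mx <- diffusion_operator(grid, props$mu_ax, props$D_x)
  Mm <- diffusion_operator(grid, props$mu_am, props$D_m)

  Bsrc <- matrix(0, N, length(sources))
  for (s in seq_along(sources)) Bsrc[src_nodes[s], s] <- sources[[s]]$amplitude
  Phi_x <- as.matrix(Matrix::solve(Mx, Bsrc))

  Bdet <- matrix(0, N, length(det_nodes))
  for (d in seq_along(det_nodes)) Bdet[det_nodes[d], d] <- 1
  G_m <- as.matrix(Matrix::solve(Mm, Bdet))

  nS <- length(sources); nD <- length(det_nodes)
  A <- matrix(0, nS * nD, N)
  for (s in seq_len(nS)) {
    A[(s - 1L) * nD + seq_len(nD), ] <- t(G_m * Phi_x[, s]) * h^2
  }
  row_index <- tibble::tibble(source = rep(seq_len(nS), each = nD),
                              detector = rep(seq_len(nD), times = nS))
  structure(list(A = A, row_index = row_index, src_nodes = src_nodes,
                 det_nodes = det_nodes, grid = grid, props = props),
            class = "fmt_sensitivity")
}

#' @export
print.fmt_sensitivity <- function(x, ...) {
  cat(sprintf("<fmt_sensitivity> %d x %d (%d sources x %d detectors -> %d nodes)\n",
              nrow(x$A), ncol(x$A), length(x$src_nodes), length(x$det_nodes), ncol(x$A)))
  invisible(x)
}

# Accept either an fmt_sensitivity or a plain matrix wherever A is needed.
as_forward_matrix <- function(A) {
  if (inherits(A, "fmt_sensitivity")) A$A else as.matrix(A)
}

#' Simulate boundary measurements from a ground-truth yield
#'
#' Computes `phi_m = A x_true + e` with `e` zero-mean Gaussian of standard
#' deviation `noise_level * mean(|A x_true|)`. With a zero signal the noise
#' scale collapses to zero, so the returned vector is exactly zero; this
#' degenerate convention keeps the noise relative to signal strength.
#'
#' @param A An `fmt_sensitivity` or plain `M x N` matrix.
#' @param x_true Length-`N` nonnegative yield vector.
#' @param noise_level Noise standard deviation as a fraction of the mean
#'   absolute signal; `>= 0`.
#' @param seed Optional integer seed making the draw reproducible.
#' @return Length-`M` measurement vector.
#' @export
simulate_measurements <- function(A, x_true, noise_level = 0, seed = NULL) {
  A <- as_forward_matrix(A)
  if (length(x_true) != ncol(A)) {
    stop(sprintf("shape error: x_true has length %d but A has %d columns",
                 length(x_true), ncol(A)))
  }
  if (noise_level < 0) stop("noise_level must be >= 0")
  phi <- drop(A %*% x_true)
  if (noise_level > 0) {
    sigma <- noise_level * mean(abs(phi))
    phi <- phi + with_seed(seed, rnorm(length(phi), 0, sigma))
  }
  phi
}

#' Place boundary point sources one transport mean free path deep
#'
#' Distributes `n` point sources evenly along the domain perimeter and moves
#' each inward, normal to its side, by one transport mean free path
#' `1 / mu_s_prime` (the conventional depth at which a collimated beam is
#' modeled as an isotropic point source); positions are then snapped to the
#' nearest grid node by the forward solver.
#'
#' @param grid An [imaging_grid()].
#' @param n Number of sources.
#' @param mu_s_prime Reduced scattering coefficient (1/mm) setting the depth.
#' @param amplitude Source strength for each source.
#' @return List of [source_spec()] objects.
#' @export
place_sources <- function(grid, n, mu_s_prime, amplitude = 1) {
  if (n < 1L) stop("need at least one source")
  depth <- 1 / mu_s_prime
  ext <- grid_extent(grid)
  Lx <- ext[2] - ext[1]; Ly <- ext[4] - ext[3]
  per <- 2 * (Lx + Ly)
  t0 <- per / (2 * n)  # offset so sources avoid corners for small n
  lapply(seq_len(n), function(k) {
    t <- (t0 + (k - 1L) * per / n) %% per
    if (t < Lx) {                       # bottom edge, inward = +y
      p <- c(ext[1] + t, ext[3] + depth)
    } else if (t < Lx + Ly) {           # right edge, inward = -x
      p <- c(ext[2] - depth, ext[3] + (t - Lx))
    } else if (t < 2 * Lx + Ly) {       # top edge, inward = -y
      p <- c(ext[2] - (t - Lx - Ly), ext[4] - depth)
    } else {                            # left edge, inward = +x
      p <- c(ext[1] + depth, ext[4] - (t - 2 * Lx - Ly))
    }
    p[1] <- min(max(p[1], ext[1] + depth), ext[2] - depth)
    p[2] <- min(max(p[2], ext[3] + depth), ext[4] - depth)
    source_spec(p, amplitude)
  })
}

#' All-boundary detector layout
#'
#' @param grid An [imaging_grid()].
#' @return Matrix of physical positions (mm), one row per boundary node, in
#'   node order.
#' @export
boundary_detectors <- function(grid) {
  grid_coordinates(grid)[boundary_nodes(grid), , drop = FALSE]
}
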