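#' Disk-phantom specification
#'
#' Describes sparse fluorescent targets as disks on an imaging grid — the 2D
#' analogue of the spherical inclusions used in small-animal simulation
#' studies. Radii and intensities keep their physical meaning (mm, arbitrary
#' yield units).
#'
#' @param targets A data frame (or tibble) with columns `cx`, `cy` (center,
#'   mm), `radius` (mm, > 0), `intensity` (> 0); one row per disk. May be
#'   empty.
#' @param grid The [imaging_grid()] the phantom lives on.
#' @return An object of class `fmt_phantom`.
#' @export
phantom_spec <- function(targets, grid) {
  stopifnot(inherits(grid, "fmt_grid"))
  targets <- as.data.frame(targets)
  if (nrow(targets) > 0) {
    need <- c("cx", "cy", "radius", "intensity")
    if (!all(need %in% names(targets))) {
      stop("invalid spec: targets need columns cx, cy, radius, intensity")
    }
    if (any(targets$radius <= 0) || any(targets$intensity <= 0)) {
      stop("invalid spec: radii and intensities must be positive")
    }
    ext <- grid_extent(grid)
    inside <- targets$cx >= ext[1] & targets$cx <= ext[2] &
              targets$cy >= ext[3] & targets$cy <= ext[4]
    if (!all(inside)) stop("invalid spec: target center outside the imaging domain")
  }
  structure(list(targets = tibble::as_tibble(targets), grid = grid),
            class = "fmt_phantom")
}

#' Rasterize a disk phantom onto its grid
#'
#' Each node receives the summed intensity of every disk whose radius covers
#' the node's physical coordinate; nodes outside all disks are 0.
#'
#' @param spec An [phantom_spec()] object.
#' @return Numeric yield vector of length `nx * ny` in row-major node order.
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "fmt_phantom"))
  co <- grid_coordinates(spec$grid)
  x <- numeric(nrow(co))
  for (t in seq_len(nrow(spec$targets))) {
    tg <- spec$targets[t, ]
    inside <- (co[, 1] - tg$cx)^2 + (co[, 2] - tg$cy)^2 <= tg$radius^2
    x[inside] <- x[inside] + tg$intensity
  }
  x
}

#' Scenario configuration for a full synthetic FMT study
#'
#' Collects everything needed to simulate a forward problem end to end:
#' domain and grid, homogeneous optical properties, source count, detector
#' layout, targets, and the noise model. Defaults describe the package's
#' reference desk-scale setup: a 20 mm x 20 mm domain on a 32 x 32 grid,
#' murine-muscle optics, 5 boundary sources placed one transport mean free
#' path deep, detectors on every boundary node, and a single centered disk
#' target of radius 1.5 mm.
#'
#' @param nx,ny Grid node counts. Default 32 x 32.
#' @param side_mm Physical side length of the square domain (mm). Default 20.
#' @param optics An [optical_properties()] object. Default [muscle_optics()].
#' @param n_sources Number of boundary sources. Default 5.
#' @param targets Data frame of disks as in [phantom_spec()]. Default one
#'   disk of radius 1.5 mm, intensity 1, at the domain center.
#' @param noise_level Relative measurement noise. Default 0.
#' @param seed Integer seed controlling the noise draw. Default 1.
#' @param robin Robin boundary factor. Default 1.
#' @return A list of class `fmt_scenario_config`.
#' @export
scenario_config <- function(nx = 32L, ny = 32L, side_mm = 20,
                            optics = muscle_optics(), n_sources = 5L,
                            targets = NULL, noise_level = 0, seed = 1L,
                            robin = 1) {
  if (is.null(targets)) {
    targets <- data.frame(cx = side_mm / 2, cy = side_mm / 2,
                          radius = 1.5, intensity = 1)
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), side_mm = side_mm,
                 optics = optics, n_sources = as.integer(n_sources),
                 targets = as.data.frame(targets),
                 noise_level = noise_level, seed = as.integer(seed),
                 robin = robin),
            class = "fmt_scenario_config")
}

#' @rdname scenario_config
#' @details `two_target_config()` is the two-inclusion layout used for the
#'   convergence comparison: two disks of radius 1 mm at (13, 12) and
#'   (13, 6) mm with unit intensity.
#' @param ... Passed on to [scenario_config()].
#' @export
two_target_config <- function(noise_level = 0.01, seed = 1L, ...) {
  scenario_config(
    targets = data.frame(cx = c(13, 13), cy = c(12, 6),
                         radius = 1, intensity = 1),
    noise_level = noise_level, seed = seed, ...
  )
}

#' Build a complete synthetic FMT scenario
#'
#' Constructs the grid, places sources one transport mean free path beneath
#' the boundary, lays detectors on every boundary node, assembles the
#' sensitivity matrix, rasterizes the ground-truth phantom and simulates
#' (optionally noisy) measurements. The bundle is fully determined by the
#' configuration, including its seed.
#'
#' @param config An [scenario_config()].
#' @return A list of class `fmt_scenario` with fields `A`
#'   (`fmt_sensitivity`), `grid`, `x_true`, `phi_m`, `phantom`, `sources`,
#'   `noise_level`, `seed`, `config`.
#' @export
make_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "fmt_scenario_config"))
  spacing <- config$side_mm / (config$nx - 1L)
  grid <- imaging_grid(config$nx, config$ny, spacing, origin = c(0, 0),
                       robin = config$robin)
  sources <- place_sources(grid, config$n_sources, config$optics$mu_sx_prime)
  detectors <- boundary_detectors(grid)
  A <- assemble_sensitivity_matrix(grid, config$optics, sources, detectors)
  phantom <- phantom_spec(config$targets, grid)
  x_true <- rasterize_phantom(phantom)
  phi_m <- simulate_measurements(A, x_true, config$noise_level, config$seed)
  structure(list(A = A, grid = grid, x_true = x_true, phi_m = phi_m,
                 phantom = phantom, sources = sources,
                 noise_level = config$noise_level, seed = config$seed,
                 config = config),
            class = "fmt_scenario")
}

#' @export
print.fmt_scenario <- function(x, ...) {
  cat(sprintf("<fmt_scenario> %d x %d grid, %d targets, A: %d x %d, noise %.3g, seed %d\n",
              x$grid$nx, x$grid$ny, nrow(x$phantom$targets),
              nrow(x$A$A), ncol(x$A$A), x$noise_level, x$seed))
  invisible(x)
}

#' Random linear system with a controlled singular spectrum
#'
#' Abstract solver fixture independent of the optics: `A = U S V'` with
#' orthonormal random factors and either a flat singular spectrum
#' (near-orthogonal rows, friendly to Kaczmarz) or a geometric decay
#' (`decay^(i-1)`, increasingly ill-conditioned). The ground truth is
#' sparse and nonnegative and the measurements are consistent.
#'
#' @param M,N System dimensions, `>= 1`.
#' @param condition_profile `"flat"` or `"geometric"`.
#' @param decay Ratio of the geometric spectrum. Default 0.8.
#' @param n_nonzero Support size of the ground truth; default
#'   `max(1, round(0.05 * N))`.
#' @param seed Integer seed.
#' @return List with `A`, `x_true`, `phi_m`.
#' @export
make_random_system <- function(M, N, condition_profile = c("flat", "geometric"),
                               decay = 0.8, n_nonzero = NULL, seed = 1L) {
  condition_profile <- match.arg(condition_profile)
  if (M < 1L || N < 1L) stop("M and N must be >= 1")
  if (is.null(n_nonzero)) n_nonzero <- max(1L, round(0.05 * N))
  n_nonzero <- min(as.integer(n_nonzero), N)
  with_seed(seed, {
    r <- min(M, N)
    U <- qr.Q(qr(matrix(rnorm(M * r), M, r)))
    V <- qr.Q(qr(matrix(rnorm(N * r), N, r)))
    s <- switch(condition_profile,
                flat = rep(1, r),
                geometric = decay^(seq_len(r) - 1L))
    A <- U %*% (s * t(V))
    x_true <- numeric(N)
    x_true[sample.int(N, n_nonzero)] <- abs(rnorm(n_nonzero)) + 0.5
    list(A = A, x_true = x_true, phi_m = drop(A %*% x_true))
  })
}
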