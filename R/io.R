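#' Read and write matrices in MatrixMarket format
#'
#' `read_matrix()` accepts both `coordinate` and `array` real general files
#' and returns a dense base matrix; `write_matrix()` writes coordinate
#' format at full double precision. Coordinate files go through
#' [Matrix::readMM()]; the array layout (column-major dense listing), which
#' that reader does not handle, is parsed here.
#'
#' @param path File path, conventionally `.mtx`.
#' @param mat Matrix to write (base matrix or `Matrix`).
#' @return `read_matrix()` returns a dense numeric matrix; `write_matrix()`
#'   returns `path` invisibly.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("parse error: file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("parse error: %s line 1: empty file", path))
  hdr <- tolower(strsplit(trimws(first), "\\s+")[[1]])
  if (length(hdr) < 4L || hdr[1] != "%%matrixmarket" || hdr[2] != "matrix") {
    stop(sprintf("parse error: %s line 1: not a MatrixMarket header", path))
  }
  fmt <- hdr[3]
  if (fmt == "coordinate") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stop(sprintf("parse error: %s: %s",
                                                   path, conditionMessage(e))))
    return(as.matrix(m))
  }
  if (fmt != "array") stop(sprintf("parse error: %s line 1: unsupported format '%s'", path, fmt))
  lines <- readLines(path)
  body <- which(!startsWith(trimws(lines), "%") & nzchar(trimws(lines)))
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[body[1]]), "\\s+")[[1]]))
  if (length(dims) != 2L || anyNA(dims)) {
    stop(sprintf("parse error: %s line %d: expected 'nrow ncol'", path, body[1]))
  }
  vals_lines <- body[-1]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[vals_lines]), "\\s+"))))
  if (anyNA(vals) || length(vals) != prod(dims)) {
    stop(sprintf("parse error: %s: expected %d numeric entries, got %d valid",
                 path, prod(dims), sum(!is.na(vals))))
  }
  matrix(vals, nrow = dims[1], ncol = dims[2])  # array format is column-major
}

#' @rdname read_matrix
#' @export
write_matrix <- function(mat, path) {
  mat <- as_forward_matrix(mat)
  Matrix::writeMM(as(as(mat, "generalMatrix"), "CsparseMatrix"), path)
  invisible(path)
}

#' Read and write vectors as single-column CSV
#'
#' The one-line header names the ordering of the entries (default
#' `value_row_major_node_order`), making files self-describing.
#'
#' @param path File path.
#' @param vec Numeric vector to write.
#' @param name Header name used when writing.
#' @return `read_vector()` returns a numeric vector; `write_vector()` returns
#'   `path` invisibly.
#' @export
read_vector <- function(path) {
  if (!file.exists(path)) stop(sprintf("parse error: file not found: %s", path))
  df <- tryCatch(read.csv(path, colClasses = "character"),
                 error = function(e) stop(sprintf("parse error: %s: %s",
                                                  path, conditionMessage(e))))
  if (ncol(df) != 1L) stop(sprintf("parse error: %s: expected a single column", path))
  raw <- df[[1]]
  vals <- suppressWarnings(as.numeric(raw))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("parse error: %s row %d: non-numeric cell '%s'", path, bad, raw[bad]))
  }
  vals
}

#' @rdname read_vector
#' @export
write_vector <- function(vec, path, name = "value_row_major_node_order") {
  df <- data.frame(x = format(as.numeric(vec), digits = 17, trim = TRUE,
                              scientific = NA))
  names(df) <- name
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write flat key-value scenario configuration files
#'
#' One `key = value` pair per line; `#` starts a comment. Recognized keys
#' (units in brackets): `nx`, `ny` (nodes), `side_mm` (mm), `n_sources`,
#' `noise_level` (fraction of mean signal), `seed`, `robin`
#' (dimensionless), `mu_ax`, `mu_sx_prime`, `mu_am`, `mu_sm_prime` (1/mm),
#' and per-target `target<k>_cx`, `target<k>_cy` (mm), `target<k>_radius`
#' (mm), `target<k>_intensity`. Unknown keys are rejected by name.
#'
#' @param path File path.
#' @param config An `fmt_scenario_config` to write.
#' @return `read_scenario_config()` returns an [scenario_config()];
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("parse error: file not found: %s", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  if (any(lengths(kv) != 2L)) {
    stop(sprintf("parse error: %s: every line must be 'key = value'", path))
  }
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  scalar_keys <- c("nx", "ny", "side_mm", "n_sources", "noise_level", "seed",
                   "robin", "mu_ax", "mu_sx_prime", "mu_am", "mu_sm_prime")
  target_re <- "^target([0-9]+)_(cx|cy|radius|intensity)$"
  known <- keys %in% scalar_keys | grepl(target_re, keys)
  if (!all(known)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(keys[!known], collapse = ", ")))
  }
  num <- suppressWarnings(as.numeric(vals))
  if (anyNA(num)) {
    bad <- which(is.na(num))[1]
    stop(sprintf("parse error: %s: non-numeric value for key '%s'", path, keys[bad]))
  }
  get <- function(k, default) if (k %in% keys) num[keys == k][1] else default

  tk <- grep(target_re, keys)
  targets <- NULL
  if (length(tk) > 0) {
    ids <- sort(unique(as.integer(sub(target_re, "\\1", keys[tk]))))
    targets <- do.call(rbind, lapply(ids, function(i) {
      g <- function(f) {
        k <- sprintf("target%d_%s", i, f)
        if (!k %in% keys) stop(sprintf("parse error: %s: missing key '%s'", path, k))
        num[keys == k][1]
      }
      data.frame(cx = g("cx"), cy = g("cy"),
                 radius = g("radius"), intensity = g("intensity"))
    }))
  }
  optics <- optical_properties(get("mu_ax", 0.0052), get("mu_sx_prime", 1.08),
                               get("mu_am", 0.0068), get("mu_sm_prime", 1.03))
  scenario_config(nx = get("nx", 32), ny = get("ny", 32),
                  side_mm = get("side_mm", 20), optics = optics,
                  n_sources = get("n_sources", 5), targets = targets,
                  noise_level = get("noise_level", 0), seed = get("seed", 1),
                  robin = get("robin", 1))
}

#' @rdname read_scenario_config
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "fmt_scenario_config"))
  fmtv <- function(v) format(v, digits = 17, trim = TRUE)
  lines <- c(
    sprintf("nx = %d", config$nx), sprintf("ny = %d", config$ny),
    sprintf("side_mm = %s", fmtv(config$side_mm)),
    sprintf("n_sources = %d", config$n_sources),
    sprintf("noise_level = %s", fmtv(config$noise_level)),
    sprintf("seed = %d", config$seed),
    sprintf("robin = %s", fmtv(config$robin)),
    sprintf("mu_ax = %s", fmtv(config$optics$mu_ax)),
    sprintf("mu_sx_prime = %s", fmtv(config$optics$mu_sx_prime)),
    sprintf("mu_am = %s", fmtv(config$optics$mu_am)),
    sprintf("mu_sm_prime = %s", fmtv(config$optics$mu_sm_prime))
  )
  for (i in seq_len(nrow(config$targets))) {
    tg <- config$targets[i, ]
    lines <- c(lines,
               sprintf("target%d_cx = %s", i, fmtv(tg$cx)),
               sprintf("target%d_cy = %s", i, fmtv(tg$cy)),
               sprintf("target%d_radius = %s", i, fmtv(tg$radius)),
               sprintf("target%d_intensity = %s", i, fmtv(tg$intensity)))
  }
  writeLines(lines, path)
  invisible(path)
}
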