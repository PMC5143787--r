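#' Plot the convergence trace of a Kaczmarz fit
#'
#' Shows relative deviation, Dice and sparsity (whichever the trace holds)
#' against the iteration index, one panel per metric — the standard way
#' convergence of these reconstructions is inspected.
#'
#' @param object An `scpk_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scpk_fit <- function(object, ...) {
  tr <- object$trace
  metrics <- c(delta = "relative deviation", dice_support = "Dice (support)",
               sparsity = "sparsity", update_norm = "update norm")
  keep <- names(metrics)[vapply(names(metrics),
                                function(m) any(!is.na(tr[[m]])), logical(1))]
  long <- do.call(rbind, lapply(keep, function(m) {
    data.frame(k = tr$k, metric = metrics[[m]], value = tr[[m]])
  }))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "iteration (full sweep)", y = NULL,
                  title = sprintf("%s convergence trace", object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a yield vector as an image over its grid
#'
#' @param x Yield vector in row-major node order.
#' @param grid The [imaging_grid()] it lives on.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_yield <- function(x, grid, title = "fluorescent yield") {
  stopifnot(inherits(grid, "fmt_grid"))
  co <- grid_coordinates(grid)
  df <- data.frame(x = co[, 1], y = co[, 2], value = as.numeric(x))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", fill = "yield", title = title) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_yield Ground truth, source and detector layout of a
#'   scenario.
#' @param object An `fmt_scenario`.
#' @param ... Unused.
#' @export
autoplot.fmt_scenario <- function(object, ...) {
  p <- plot_yield(object$x_true, object$grid, title = "scenario ground truth")
  src <- do.call(rbind, lapply(object$sources, function(s) s$position))
  det <- grid_coordinates(object$grid)[object$A$det_nodes, , drop = FALSE]
  p +
    ggplot2::geom_point(data = data.frame(x = det[, 1], y = det[, 2]),
                        ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 0, size = 0.8,
                        color = "grey60") +
    ggplot2::geom_point(data = data.frame(x = src[, 1], y = src[, 2]),
                        ggplot2::aes(x = .data$x, y = .data$y),
                        inherit.aes = FALSE, shape = 8, color = "red")
}

#' @importFrom ggplot2 .data
NULL
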