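#' Plot a monolayer mesh
#'
#' Draws the cell polygons, optionally filled by a per-cell quantity (for
#' example effective pressure or shear stress).
#'
#' @param mesh a `mono_mesh` or `vm_state`
#' @param fill optional numeric vector, one value per cell
#' @param fill_name legend title
#' @return a ggplot object
#' @export
plot_monolayer <- function(mesh, fill = NULL, fill_name = "value") {
  if (inherits(mesh, "vm_state")) mesh <- vm_mesh(mesh)
  top <- mesh$topology
  zl <- lengths(top$cells)
  df <- tibble::tibble(
    cell = rep(seq_along(top$cells), zl),
    x = mesh$geometry$r[unlist(top$cells), 1],
    y = mesh$geometry$r[unlist(top$cells), 2])
  if (!is.null(fill)) {
    df$fill <- rep(fill, zl)
    p <- ggplot2::ggplot(df, ggplot2::aes(x, y, group = cell, fill = fill)) +
      ggplot2::geom_polygon(colour = "grey30", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(name = fill_name)
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x, y, group = cell)) +
      ggplot2::geom_polygon(fill = "grey90", colour = "grey30",
                            linewidth = 0.2)
  }
  p + ggplot2::coord_equal() + ggplot2::theme_void()
}

#' Plot an edge vector field over a mesh
#'
#' Arrows at the edge centroids (or edge-link intersections) of the retained
#' edges.
#'
#' @param ops `mono_operators`
#' @param v vector-field matrix over retained edges
#' @param scale arrow length multiplier
#' @return a ggplot object
#' @export
plot_edge_field <- function(ops, v, scale = 1) {
  ops <- as_operators(ops)
  cm <- ops$mesh$geometry$c_mid[ops$idx_e, , drop = FALSE]
  df <- tibble::tibble(x = cm[, 1], y = cm[, 2],
                       xend = cm[, 1] + scale * v[, 1],
                       yend = cm[, 2] + scale * v[, 2])
  plot_monolayer(ops$mesh) +
    ggplot2::geom_segment(
      data = df,
      ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
      inherit.aes = FALSE,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm")),
      colour = "firebrick", linewidth = 0.3)
}

#' Radial upper-bound scatter with its fitted slope
#'
#' Log-log scatter of a non-negative quantity against distance, overlaying
#' the per-bin maxima and the fitted power law from [upper_bound_slope()].
#'
#' @param values,radii as in [upper_bound_slope()]
#' @param fit optional precomputed fit (computed if missing)
#' @param ... passed to [upper_bound_slope()]
#' @return a ggplot object
#' @export
plot_upper_bound <- function(values, radii, fit = NULL, ...) {
  if (is.null(fit)) fit <- upper_bound_slope(values, radii, ...)
  df <- tibble::tibble(r = radii, v = values)
  df <- df[df$v > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(r, v)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_point(data = fit$bins,
                        ggplot2::aes(r, max_value), colour = "firebrick") +
    ggplot2::geom_line(
      data = tibble::tibble(
        r = fit$bins$r,
        v = 10^(stats::predict(stats::lm(log10(max_value) ~ log10(r),
                                         data = fit$bins)))),
      ggplot2::aes(r, v), colour = "firebrick", linetype = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from ablation", y = "value",
                  subtitle = sprintf("upper-bound slope %.2f +- %.2f",
                                     fit$slope, fit$stderr)) +
    ggplot2::theme_minimal()
}

#' Autoplot method for Hodge decompositions
#'
#' Shows the magnitude of the residual field over the mesh.
#' @param object a `mono_hodge`
#' @param ops the `mono_operators` the decomposition was computed with
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.mono_hodge <- function(object, ops, ...) {
  plot_edge_field(ops, object$residual, ...)
}
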