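# Basic 2D "shadow" plots of the tetrahedral colour space: occupancy of the
# yz (side) or yx (bottom) projection grid, with the tetrahedron's edges
# drawn for orientation.

.tetra_edges_2d <- function(plane) {
  v <- tetra_vertices()
  keep <- if (plane == "yz") c(2, 3) else c(2, 1)
  idx <- utils::combn(4, 2)
  do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
    a <- v[idx[1, k], keep]; b <- v[idx[2, k], keep]
    data.frame(x = a[1], y = a[2], xend = b[1], yend = b[2])
  }))
}

#' Shadow plot of colour-space occupancy
#'
#' Tile plot of 2D projection-grid counts (warmer = more occupied), the
#' two-dimensional view of the tetrahedron from the side (`"yz"`) or from
#' above (`"yx"`).
#'
#' @param points Colour-space points (`x, y, z`), or a [project_2d()] grid.
#' @param plane `"yz"` or `"yx"`.
#' @param cell_size Projection cell edge.
#' @return A ggplot object.
#' @export
plot_shadow <- function(points, plane = c("yz", "yx"), cell_size = 0.022) {
  plane <- match.arg(plane)
  g <- if (!is.null(attr(points, "plane"))) points
       else project_2d(points, plane, cell_size)
  cs <- attr(g, "cell_size")
  df <- data.frame(a = (g$i1 + 0.5) * cs, b = (g$i2 + 0.5) * cs,
                   count = g$count)
  lab <- if (plane == "yz") c("y", "z") else c("y", "x")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b,
                                   fill = .data$count)) +
    ggplot2::geom_tile(width = cs, height = cs) +
    ggplot2::geom_segment(
      data = .tetra_edges_2d(plane),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      inherit.aes = FALSE, linewidth = 0.3, colour = "grey40") +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "patches") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = lab[1], y = lab[2],
                  title = sprintf("%s shadow (cell %g)", plane, cs)) +
    ggplot2::theme_minimal()
}
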