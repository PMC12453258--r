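# Base-graphics summaries: migration surface maps with long-range arrows,
# source likelihood surfaces, and observed-vs-fitted diagnostics.

# symmetric log2(w / mean(w)) colour scale (brown = low, blue = high)
edge_colours <- function(w) {
  lr <- log2(w / mean(w))
  lim <- max(abs(lr), 1e-6)
  pal <- grDevices::colorRampPalette(c("#8c510a", "#f5f5f5", "#01665e"))(101)
  pal[ceiling((lr + lim) / (2 * lim) * 100) + 1]
}

#' Plot a fitted migration surface
#'
#' Edges are coloured by log2 of their weight relative to the mean weight
#' (blue/green high, brown low). Fitted long-range edges are drawn as arrows
#' from source to destination, solid when L_r > 10 and dashed otherwise,
#' filled on a white-to-black scale by the source fraction, and thinner with
#' increasing rank.
#'
#' @param x a `migration_surface` or `lre_fit`.
#' @param edges optional list of `long_range_edge` objects to overlay.
#' @param ... passed to [plot()].
#' @export
plot.migration_surface <- function(x, edges = NULL, ...) {
  grid <- x$grid
  plot(grid$node_coords, type = "n", asp = 1, xlab = "lon", ylab = "lat", ...)
  cols <- edge_colours(x$w)
  segments(grid$node_coords[grid$edges[, 1], 1],
           grid$node_coords[grid$edges[, 1], 2],
           grid$node_coords[grid$edges[, 2], 1],
           grid$node_coords[grid$edges[, 2], 2],
           col = cols, lwd = 2)
  points(grid$node_coords[x$demes, , drop = FALSE], pch = 21, bg = "grey40",
         cex = 0.9)
  if (!is.null(edges)) draw_lre_arrows(grid, edges)
  invisible(x)
}

draw_lre_arrows <- function(grid, edges) {
  for (k in seq_along(edges)) {
    e <- edges[[k]]
    fill <- grDevices::grey(1 - e$c)   # white at c = 0, black at c = 1
    lty <- if (isTRUE(e$supported) || (!is.null(e$Lr) && e$Lr > 10)) 1 else 2
    arrows(grid$node_coords[e$source, 1], grid$node_coords[e$source, 2],
           grid$node_coords[e$dest, 1], grid$node_coords[e$dest, 2],
           length = 0.12, lwd = max(3.5 - 0.5 * (k - 1), 1), lty = lty,
           col = fill)
  }
}

#' @export
plot.lre_fit <- function(x, ...) {
  plot(x$surface, edges = x$edges, ...)
}

#' Plot a per-node source likelihood surface
#'
#' Nodes are shaded by log-likelihood (darker = higher, 2-unit drop marked).
#'
#' @param scan result of [prefit_scan()].
#' @param grid the `spatial_grid`.
#' @param ... passed to [plot()].
#' @export
plot_likelihood_surface <- function(scan, grid, ...) {
  ll <- scan$loglik - max(scan$loglik)
  shade <- pmax(pmin(1 + ll / 20, 1), 0)
  pal <- grDevices::colorRampPalette(c("white", "darkgreen"))(101)
  plot(grid$node_coords, type = "n", asp = 1, xlab = "lon", ylab = "lat", ...)
  points(grid$node_coords[scan$node, , drop = FALSE], pch = 22,
         bg = pal[ceiling(shade * 100) + 1], cex = 1.6)
  top <- scan$node[ll >= -2]
  points(grid$node_coords[top, , drop = FALSE], pch = 0, cex = 1.9,
         col = "red")
  invisible(scan)
}

#' Observed versus fitted distance diagnostic
#'
#' @param D_hat,Delta matched o x o matrices.
#' @param highlight optional pair indices (into the upper triangle) drawn in
#'   red.
#' @param ... passed to [plot()].
#' @export
plot_fit_diagnostic <- function(D_hat, Delta, highlight = NULL, ...) {
  x <- Delta[upper.tri(Delta)]
  y <- D_hat[upper.tri(D_hat)]
  plot(x, y, pch = 16, cex = 0.6, col = "grey30",
       xlab = "fitted distance", ylab = "observed distance", ...)
  if (!is.null(highlight)) points(x[highlight], y[highlight], col = "red",
                                  pch = 16, cex = 0.8)
  abline(0, 1, lty = 2)
  legend("topleft", bty = "n",
         legend = sprintf("R^2 = %.3f", model_r_squared(D_hat, Delta)))
  invisible(NULL)
}
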