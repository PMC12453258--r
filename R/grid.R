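#' Construct a triangular deme lattice over a bounding polygon
#'
#' Builds a planar triangular lattice (offset rows, up to six neighbours per
#' node) with the given node spacing, keeps the nodes falling inside the
#' polygon, and connects lattice-adjacent nodes. The graph over these demes is
#' the support of the effective migration surface.
#'
#' @param polygon matrix or data frame with two columns (lon, lat) giving the
#'   vertices of a simple polygon; the last vertex need not repeat the first.
#' @param spacing numeric > 0, distance between adjacent nodes in degrees.
#' @return A `spatial_grid` object: list with `node_ids` (integer), `node_coords`
#'   (n x 2 matrix, lon/lat) and `edges` (m x 2 integer matrix, each row an
#'   unordered pair of node ids, first < second).
#' @examples
#' g <- build_grid(cbind(c(0, 3, 3, 0), c(0, 0, 2, 2)), spacing = 1)
#' plot(g)
#' @export
build_grid <- function(polygon, spacing) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3)
    stop("polygon must have >= 3 vertices with columns (lon, lat)")
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive scalar")

  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  dy <- spacing * sqrt(3) / 2
  rows <- seq(yr[1], yr[2] + 1e-9, by = dy)
  pts <- do.call(rbind, lapply(seq_along(rows), function(r) {
    off <- if (r %% 2 == 0) spacing / 2 else 0
    xs <- seq(xr[1] + off, xr[2] + 1e-9, by = spacing)
    if (!length(xs)) return(NULL)
    cbind(xs, rows[r], r - 1L, round((xs - xr[1] - off) / spacing))
  }))
  keep <- point_in_polygon(pts[, 1], pts[, 2], polygon)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) stop("polygon too small: fewer than 2 lattice nodes inside")

  grid <- lattice_from_rowcol(pts[, 3], pts[, 4], pts[, 1], pts[, 2])
  comp <- graph_components(nrow(grid$node_coords), grid$edges)
  if (max(comp) > 1) {
    # keep the largest connected component; clipping can strand isolated nodes
    big <- which.max(tabulate(comp))
    grid <- subset_grid(grid, which(comp == big))
  }
  grid
}

#' Regular triangular lattice with given dimensions
#'
#' Convenience constructor used throughout the simulation scenarios: an
#' `nrow` x `ncol` lattice with unit spacing, rows offset by half a unit so
#' every interior node has six neighbours.
#'
#' @param nrow,ncol lattice dimensions (demes).
#' @return a `spatial_grid`.
#' @export
triangular_lattice <- function(nrow, ncol) {
  stopifnot(nrow >= 1, ncol >= 1, nrow * ncol >= 2)
  rc <- expand.grid(col = 0:(ncol - 1), row = 0:(nrow - 1))
  x <- rc$col + ifelse(rc$row %% 2 == 1, 0.5, 0)
  y <- rc$row * sqrt(3) / 2
  lattice_from_rowcol(rc$row, rc$col, x, y)
}

# Build edges from integer (row, col) lattice indices. Offset-row triangular
# adjacency: same-row neighbours, plus two diagonal neighbours in adjacent rows
# whose identity depends on row parity.
lattice_from_rowcol <- function(row, col, x, y) {
  row <- as.integer(row); col <- as.integer(col)
  key <- paste(row, col)
  idx <- seq_along(row)
  names(idx) <- key
  nb_of <- function(r, cc) {
    odd <- r %% 2 == 1
    rbind(
      c(r, cc - 1), c(r, cc + 1),
      if (odd) c(r - 1, cc) else c(r - 1, cc - 1),
      if (odd) c(r - 1, cc + 1) else c(r - 1, cc),
      if (odd) c(r + 1, cc) else c(r + 1, cc - 1),
      if (odd) c(r + 1, cc + 1) else c(r + 1, cc)
    )
  }
  edges <- vector("list", length(idx))
  for (i in idx) {
    nb <- nb_of(row[i], col[i])
    j <- idx[paste(nb[, 1], nb[, 2])]
    j <- j[!is.na(j) & j > i]
    if (length(j)) edges[[i]] <- cbind(i, j)
  }
  edges <- do.call(rbind, edges)
  structure(list(node_ids = idx, node_coords = cbind(lon = x, lat = y),
                 edges = unname(edges), row = row, col = col),
            class = "spatial_grid")
}

subset_grid <- function(grid, keep) {
  keep <- sort(keep)
  map <- integer(nrow(grid$node_coords)); map[keep] <- seq_along(keep)
  e <- grid$edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  structure(list(node_ids = seq_along(keep),
                 node_coords = grid$node_coords[keep, , drop = FALSE],
                 edges = cbind(map[e[, 1]], map[e[, 2]]),
                 row = grid$row[keep], col = grid$col[keep]),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat("spatial_grid:", nrow(x$node_coords), "demes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' @export
plot.spatial_grid <- function(x, ...) {
  plot(x$node_coords, pch = 16, cex = 0.6, asp = 1,
       xlab = "lon", ylab = "lat", ...)
  segments(x$node_coords[x$edges[, 1], 1], x$node_coords[x$edges[, 1], 2],
           x$node_coords[x$edges[, 2], 1], x$node_coords[x$edges[, 2], 2],
           col = "grey70")
  invisible(x)
}

# Ray-casting point-in-polygon (boundary points count as inside).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  boundary <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    boundary <- boundary |
      (abs((xj - xi) * (py - yi) - (yj - yi) * (px - xi)) < 1e-12 &
         px >= pmin(xi, xj) - 1e-12 & px <= pmax(xi, xj) + 1e-12 &
         py >= pmin(yi, yj) - 1e-12 & py <= pmax(yi, yj) + 1e-12)
    j <- i
  }
  inside | boundary
}

# Connected components by BFS; returns component label per node.
graph_components <- function(n, edges) {
  adj <- adjacency_list(n, edges)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    k <- k + 1L
    queue <- s; comp[s] <- k
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- k
      queue <- c(queue, new)
    }
  }
  comp
}

adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# Graph (hop) distance from a node to all others on the unweighted grid.
graph_hop_distances <- function(grid, from) {
  n <- nrow(grid$node_coords)
  adj <- adjacency_list(n, grid$edges)
  d <- rep(NA_integer_, n); d[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]][is.na(d[adj[[v]]])]
    d[nb] <- d[v] + 1L
    queue <- c(queue, nb)
  }
  d
}

#' Assign samples to their nearest demes
#'
#' Each sample is mapped to the grid node nearest to its coordinates by
#' great-circle distance; ties go to the lower node id.
#'
#' @param sample_coords n x 2 matrix of sample (lon, lat).
#' @param grid a `spatial_grid`.
#' @return A `sample_assignment`: list with `deme_of_sample` (node id per
#'   sample), `observed_demes` (sorted unique sampled node ids) and `counts`
#'   (samples per observed deme).
#' @export
assign_samples <- function(sample_coords, grid) {
  sample_coords <- as.matrix(sample_coords)
  if (nrow(sample_coords) == 0) stop("no samples to assign")
  if (!all(is.finite(sample_coords))) stop("sample coordinates must be finite")
  nodes <- grid$node_coords
  deme <- vapply(seq_len(nrow(sample_coords)), function(i) {
    d <- geosphere::distHaversine(sample_coords[i, ], nodes)
    which(d <= min(d) + 1e-9)[1]  # lowest id on ties
  }, integer(1))
  observed <- sort(unique(deme))
  structure(list(deme_of_sample = deme, observed_demes = observed,
                 counts = as.integer(table(factor(deme, levels = observed)))),
            class = "sample_assignment")
}

#' Graph Laplacian of a weighted grid
#'
#' @param W symmetric non-negative weight matrix with zero diagonal, support on
#'   the grid edges.
#' @return L = diag(W1) - W.
#' @export
graph_laplacian <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) stop("edge weights must be non-negative")
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  diag(W) <- 0
  diag(rowSums(W)) - W
}

# Dense weight matrix from per-edge weights.
weight_matrix <- function(grid, w) {
  n <- nrow(grid$node_coords)
  W <- matrix(0, n, n)
  W[grid$edges] <- w
  W[grid$edges[, 2:1, drop = FALSE]] <- w
  W
}

# Moore-Penrose pseudo-inverse of a connected-graph Laplacian via the grounded
# rank-one correction: (L + 11'/n)^{-1} - 11'/n.
laplacian_pinv <- function(L) {
  n <- nrow(L)
  J <- matrix(1 / n, n, n)
  solve(L + J) - J
}

#' Resistance distances between all nodes
#'
#' Effective resistance R_ij = L+_ii + L+_jj - 2 L+_ij from the pseudo-inverse
#' of the graph Laplacian; proxy for lineage commute time on the surface.
#'
#' @param L a connected-graph Laplacian (see [graph_laplacian()]).
#' @return symmetric matrix of resistance distances with zero diagonal.
#' @export
resistance_matrix <- function(L) {
  n <- nrow(L)
  comp <- graph_components(n, which(upper.tri(L) & L != 0, arr.ind = TRUE))
  if (max(comp) > 1) stop("graph is disconnected: resistance undefined across components")
  Lp <- laplacian_pinv(L)
  d <- diag(Lp)
  R <- outer(d, d, "+") - 2 * Lp
  R[R < 0] <- 0  # clip numerical negatives
  diag(R) <- 0
  (R + t(R)) / 2
}

#' Observed genetic distances between demes
#'
#' Deme-level allele frequencies are the within-deme genotype means divided by
#' two; the distance between demes i and j is the mean squared frequency
#' difference across SNPs. The overall scale is absorbed by the convention
#' sigma* = 1 in the Wishart likelihood, so only consistency across demes
#' matters.
#'
#' @param genotypes n x p integer matrix, values 0/1/2 (minor-allele dosage).
#' @param assignment a `sample_assignment`.
#' @param impute if TRUE, missing genotypes are replaced by the per-SNP mean;
#'   if FALSE (default), any missing genotype is an error.
#' @return A `distance_bundle`: list with `D_hat` (o x o), `p` (SNP count) and
#'   the observed deme ids.
#' @export
observed_genetic_distances <- function(genotypes, assignment, impute = FALSE) {
  G <- as.matrix(genotypes)
  if (ncol(G) < 1) stop("need at least one SNP")
  if (anyNA(G)) {
    if (!impute) {
      miss <- which(is.na(G), arr.ind = TRUE)[1, ]
      stop(sprintf("missing genotype for sample %d at locus %d (set impute = TRUE to mean-impute)",
                   miss[1], miss[2]))
    }
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  demes <- assignment$observed_demes
  if (length(demes) < 2) stop("need samples from at least two demes")
  F <- t(vapply(demes, function(d) {
    colMeans(G[assignment$deme_of_sample == d, , drop = FALSE]) / 2
  }, numeric(ncol(G))))
  o <- length(demes)
  # mean squared frequency difference over SNPs
  cross <- tcrossprod(F) / ncol(G)
  self <- diag(cross)
  D <- outer(self, self, "+") - 2 * cross
  D[D < 0] <- 0
  diag(D) <- 0
  structure(list(D_hat = (D + t(D)) / 2, p = ncol(G), demes = demes),
            class = "distance_bundle")
}

#' Export / import a grid as plain-text tables
#'
#' @param grid a `spatial_grid`.
#' @param node_file,edge_file TSV paths: nodes as (id, lon, lat), edges as
#'   (id1, id2).
#' @export
write_grid <- function(grid, node_file, edge_file) {
  utils::write.table(data.frame(id = grid$node_ids,
                                lon = grid$node_coords[, 1],
                                lat = grid$node_coords[, 2]),
                     node_file, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(id1 = grid$edges[, 1], id2 = grid$edges[, 2]),
                     edge_file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(grid)
}

#' @rdname write_grid
#' @export
read_grid <- function(node_file, edge_file) {
  nodes <- utils::read.table(node_file, header = TRUE, sep = "\t")
  edges <- as.matrix(utils::read.table(edge_file, header = TRUE, sep = "\t"))
  structure(list(node_ids = nodes$id,
                 node_coords = cbind(lon = nodes$lon, lat = nodes$lat),
                 edges = unname(edges), row = NULL, col = NULL),
            class = "spatial_grid")
}
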