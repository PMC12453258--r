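# Synthetic data: exact model-based Wishart draws from a given surface, and
# stepping-stone coalescent simulations of the barrier-plus-pulse scenarios.

#' Draw an observed distance matrix from the Wishart model
#'
#' Draws `p * (-C D_hat C')` from the Wishart with scale `-C Delta' C'` and
#' `p` degrees of freedom and lifts the draw back to a symmetric zero-diagonal
#' distance matrix whose expectation is exactly `Delta'`. This inverts the
#' model likelihood, so estimates on these draws are free of coalescent noise.
#'
#' @param surface a `migration_surface` (its demes define the o x o layout).
#' @param edge optional pulse: list(source, dest, c); unsampled sources get a
#'   kriged variance unless `q_source` is given.
#' @param p number of SNPs (degrees of freedom).
#' @param seed integer seed.
#' @param q_source optional variance for an unsampled source.
#' @return o x o observed distance matrix.
#' @export
simulate_wishart <- function(surface, edge = NULL, p, seed = 1,
                             q_source = NULL) {
  demes <- surface$demes
  o <- length(demes)
  if (p < o) stop("p must be at least the number of observed demes")
  if (is.null(edge)) {
    Delta <- expected_distances(surface)
  } else {
    Lp <- surface_pinv(surface)
    V <- sort(unique(c(demes, edge$source)))
    dLp <- diag(Lp)
    R_V <- outer(dLp[V], dLp[V], "+") - 2 * Lp[V, V]
    diag(R_V) <- 0
    q_V <- numeric(length(V))
    q_V[match(demes, V)] <- surface$q
    if (!(edge$source %in% demes)) {
      if (is.null(q_source)) {
        Ro <- R_V[match(demes, V), match(demes, V)]
        vg <- fit_variogram(surface$q, Ro)
        q_source <- krige_variance(vg, R_V[match(edge$source, V),
                                           match(demes, V)], surface$q)
      }
      q_V[match(edge$source, V)] <- q_source
    }
    Delta <- post_event_distances(R_V, q_V, match(edge$source, V),
                                  match(edge$dest, V), edge$c)
    obs <- match(demes, V)
    Delta <- Delta[obs, obs]
  }
  C <- contrast_matrix(o)
  S <- -(C %*% Delta %*% t(C))
  S <- (S + t(S)) / 2
  if (any(eigen(S, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("invalid surface: projected scale matrix is not positive definite")
  set.seed(seed)
  Y <- stats::rWishart(1, df = p, Sigma = S)[, , 1] / p
  # linear lift: distance matrix with -C lift(M) C' = M and zero diagonal
  lift <- function(M) {
    B <- t(C) %*% solve(tcrossprod(C))
    Sig <- 0.5 * B %*% M %*% t(B)
    d <- diag(Sig)
    out <- outer(d, d, "+") - 2 * Sig
    diag(out) <- 0
    out
  }
  D <- Delta + lift(Y) - lift(S)
  (D + t(D)) / 2
}

#' Specify a stepping-stone simulation scenario
#'
#' The default is the validation scenario: an 8 x 12 triangular lattice with a
#' two-column low-migration barrier in the middle (scaled migration Nm = 0.1
#' in the corridors, ten-fold lower on edges touching the barrier columns),
#' deme size 1000, 1000 independent SNPs, and an instantaneous pulse of
#' fraction c from a western source into an eastern destination one
#' generation before sampling.
#'
#' @param grid_shape c(rows, cols) of the deme lattice.
#' @param barrier_cols 1-based column indices forming the low-migration band
#'   (NULL for no barrier).
#' @param Nm_corridor,Nm_barrier scaled migration rates (N * m per
#'   neighbouring pair), converted to the per-generation migration fraction
#'   m = Nm / N.
#' @param deme_size diploid size per deme (scalar or per-deme vector);
#'   overridden by the sparse sampling scheme's random sizes.
#' @param pulse list(source, dest, c, tau) in node ids / generations, or NULL.
#'   Defaults to row 4, col 3 -> row 4, col 10 with the given `c`.
#' @param c source fraction for the default pulse.
#' @param n_snps number of independent SNPs.
#' @param sampling "dense" or "sparse" (see [sampling_scheme()]).
#' @param seed integer seed for the whole scenario.
#' @return a `scenario_spec` list.
#' @export
scenario_spec <- function(grid_shape = c(8, 12), barrier_cols = 6:7,
                          Nm_corridor = 0.1, Nm_barrier = 0.01,
                          deme_size = 1000, pulse = NULL, c = 0.5,
                          n_snps = 1000, sampling = c("sparse", "dense"),
                          seed = 1) {
  sampling <- match.arg(sampling)
  ncol <- grid_shape[2]
  node_id <- function(row, col) (row - 1) * ncol + col
  if (is.null(pulse))
    pulse <- list(source = node_id(4, 3), dest = node_id(4, 10), c = c,
                  tau = 1)
  structure(list(grid_shape = grid_shape, barrier_cols = barrier_cols,
                 Nm_corridor = Nm_corridor, Nm_barrier = Nm_barrier,
                 deme_size = deme_size, pulse = pulse, n_snps = n_snps,
                 sampling = sampling, seed = seed),
            class = "scenario_spec")
}

#' Per-deme sample counts and deme sizes for the two sampling schemes
#'
#' Dense: half of all demes are sampled (always including the true source and
#' destination), 10 diploid individuals per sampled deme, all deme sizes 1000.
#' Sparse: 15% of demes are sampled at random, never the true source but
#' always the destination, with 1-10 individuals per sampled deme and deme
#' sizes drawn uniformly from (100, 10000).
#'
#' @param tag "dense" or "sparse".
#' @param grid a `spatial_grid`.
#' @param truth list with `source` and `dest` node ids.
#' @param seed integer seed.
#' @param deme_size baseline deme size (dense scheme).
#' @return list(counts, deme_sizes) with one entry per grid node.
#' @export
sampling_scheme <- function(tag = c("dense", "sparse"), grid, truth, seed = 1,
                            deme_size = 1000) {
  tag <- match.arg(tag)
  n <- nrow(grid$node_coords)
  set.seed(seed)
  counts <- integer(n)
  if (tag == "dense") {
    k <- round(0.5 * n)
    forced <- unique(c(truth$source, truth$dest))
    others <- sample(setdiff(seq_len(n), forced), k - length(forced))
    counts[c(forced, others)] <- 10L
    sizes <- rep(deme_size, n)
  } else {
    k <- round(0.15 * n)
    pool <- setdiff(seq_len(n), truth$source)
    chosen <- unique(c(truth$dest, sample(setdiff(pool, truth$dest), k - 1)))
    counts[chosen] <- sample(1:10, length(chosen), replace = TRUE)
    sizes <- stats::runif(n, 100, 10000)
  }
  list(counts = counts, deme_sizes = sizes)
}

#' Simulate genotypes on the stepping-stone lattice
#'
#' Event-driven structured coalescent with symmetric nearest-neighbour
#' migration at the scenario's scaled rates, an instantaneous backward-time
#' mass migration of fraction c from the destination to the source deme `tau`
#' generations before sampling, and one mutation per independent tree (so
#' every SNP segregates). Deterministic given the scenario seed.
#'
#' @param spec a `scenario_spec`.
#' @return list with `genotypes` (individuals x SNPs dosage matrix), `coords`
#'   (per-sample lon/lat at the deme positions), `grid`, `counts`,
#'   `deme_sizes`, and `truth` (source, dest, c, tau).
#' @export
simulate_coalescent_grid <- function(spec) {
  grid <- triangular_lattice(spec$grid_shape[1], spec$grid_shape[2])
  n <- nrow(grid$node_coords)
  scheme <- sampling_scheme(spec$sampling, grid,
                            list(source = spec$pulse$source,
                                 dest = spec$pulse$dest),
                            seed = spec$seed, deme_size = spec$deme_size)
  counts <- scheme$counts
  if (sum(counts > 0) < 2) stop("sampling scheme selected fewer than 2 demes")
  sizes <- scheme$deme_sizes
  if (length(spec$deme_size) == n) sizes <- spec$deme_size

  edge_nm <- rep(spec$Nm_corridor, nrow(grid$edges))
  if (!is.null(spec$barrier_cols) && !is.null(grid$col)) {
    col1 <- grid$col[grid$edges[, 1]] + 1L   # stored 0-based
    col2 <- grid$col[grid$edges[, 2]] + 1L
    barrier <- col1 %in% spec$barrier_cols | col2 %in% spec$barrier_cols
    edge_nm[barrier] <- spec$Nm_barrier
  }

  sample_demes <- rep(seq_len(n), counts)
  pulses <- if (!is.null(spec$pulse) && spec$pulse$c > 0) {
    matrix(c(spec$pulse$tau, spec$pulse$source, spec$pulse$dest,
             spec$pulse$c), 1, 4)
  } else matrix(numeric(0), 0, 4)

  set.seed(spec$seed)
  G <- .sim_coalescent_snps(n, grid$edges, edge_nm, sizes, sample_demes,
                            spec$n_snps, pulses)
  coords <- grid$node_coords[sample_demes, , drop = FALSE]
  list(genotypes = G, coords = coords, grid = grid, counts = counts,
       deme_sizes = sizes, sample_demes = sample_demes,
       truth = list(source = spec$pulse$source, dest = spec$pulse$dest,
                    c = spec$pulse$c, tau = spec$pulse$tau))
}

#' Hudson's FST between demes
#'
#' Ratio-of-averages Hudson estimator from allele frequencies and sample
#' sizes, for every pair of demes with at least two sampled chromosomes.
#'
#' @param genotypes individuals x SNPs dosage matrix.
#' @param deme_of_sample deme id per individual.
#' @return symmetric matrix of pairwise FST over the observed demes (deme ids
#'   as dimnames).
#' @export
hudson_fst <- function(genotypes, deme_of_sample) {
  demes <- sort(unique(deme_of_sample))
  o <- length(demes)
  freq <- matrix(0, o, ncol(genotypes))
  nchr <- numeric(o)
  for (i in seq_len(o)) {
    g <- genotypes[deme_of_sample == demes[i], , drop = FALSE]
    freq[i, ] <- colMeans(g) / 2
    nchr[i] <- 2 * nrow(g)
  }
  fst <- matrix(NA_real_, o, o, dimnames = list(demes, demes))
  for (i in seq_len(o - 1)) for (j in (i + 1):o) {
    if (nchr[i] < 2 || nchr[j] < 2) next
    p1 <- freq[i, ]; p2 <- freq[j, ]
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (nchr[i] - 1) -
      p2 * (1 - p2) / (nchr[j] - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst[i, j] <- fst[j, i] <- sum(num) / sum(den)
  }
  diag(fst) <- 0
  fst
}

#' Mean FST across the barrier
#'
#' Averages Hudson FST over sampled same-row deme pairs in the two columns
#' immediately flanking the barrier band (the nearest cross-barrier pairs, so
#' isolation by distance contributes as little as possible).
#'
#' @param sim output of [simulate_coalescent_grid()].
#' @param barrier_cols the barrier column indices used in the scenario.
#' @return mean FST over available flanking pairs (NA if none sampled).
#' @export
cross_barrier_fst <- function(sim, barrier_cols = 6:7) {
  grid <- sim$grid
  west <- min(barrier_cols) - 1L
  east <- max(barrier_cols) + 1L
  col <- grid$col + 1L
  fst <- hudson_fst(sim$genotypes, sim$sample_demes)
  demes <- as.integer(rownames(fst))
  vals <- c()
  for (r in sort(unique(grid$row))) {
    wnode <- which(grid$row == r & col == west)
    enode <- which(grid$row == r & col == east)
    if (length(wnode) && length(enode) &&
        wnode %in% demes && enode %in% demes) {
      vals <- c(vals, fst[as.character(wnode), as.character(enode)])
    }
  }
  if (!length(vals)) return(NA_real_)
  mean(vals)
}
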