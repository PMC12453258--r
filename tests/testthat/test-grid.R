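# Lattice construction, sample assignment, Laplacians, resistance distances
# and observed genetic distances.

test_that("build_grid produces connected triangular lattices of the right size", {
  sq <- build_grid(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)), spacing = 1)
  expect_gte(nrow(sq$node_coords), 4)
  expect_gte(nrow(sq$edges), 5)

  big <- triangular_lattice(8, 12)
  expect_equal(nrow(big$node_coords), 96)

  for (g in list(sq, big, triangular_lattice(3, 3))) {
    comp <- migmix:::graph_components(nrow(g$node_coords), g$edges)
    expect_equal(max(comp), 1)                       # BFS reaches all nodes
    expect_true(all(g$edges[, 1] < g$edges[, 2]))    # no dupes / self loops
    expect_false(any(duplicated(g$edges)))
  }
  expect_error(build_grid(cbind(c(0, .1, .1), c(0, 0, .1)), spacing = 1),
               "too small")
})

test_that("interior lattice nodes have six neighbours", {
  g <- triangular_lattice(5, 6)
  deg <- tabulate(c(g$edges), nbins = nrow(g$node_coords))
  interior <- g$row > 0 & g$row < 4 & g$col > 0 & g$col < 5
  expect_true(all(deg[interior] == 6))
})

test_that("assign_samples matches a brute-force nearest-node search", {
  g <- triangular_lattice(4, 5)
  # identity: a sample exactly on a node goes to that node
  a <- assign_samples(g$node_coords[7, , drop = FALSE], g)
  expect_equal(a$deme_of_sample, 7)

  set.seed(1)
  pts <- cbind(runif(10, 0, 4), runif(10, 0, 2))
  a <- assign_samples(pts, g)
  brute <- vapply(seq_len(10), function(i) {
    d <- geosphere::distHaversine(pts[i, ], g$node_coords)
    which.min(d)
  }, integer(1))
  expect_equal(a$deme_of_sample, brute)
  expect_equal(a$observed_demes, sort(unique(brute)))

  # tie between two equidistant nodes resolves to the lower id
  mid <- (g$node_coords[1, ] + g$node_coords[2, ]) / 2
  expect_equal(assign_samples(rbind(mid), g)$deme_of_sample, 1)
  expect_error(assign_samples(matrix(numeric(0), 0, 2), g), "no samples")
})

test_that("graph_laplacian follows diag(W1) - W", {
  W2 <- matrix(c(0, 3, 3, 0), 2)
  expect_equal(graph_laplacian(W2), matrix(c(3, -3, -3, 3), 2))

  set.seed(3)
  W <- matrix(0, 5, 5)
  W[upper.tri(W)] <- runif(10)
  W <- W + t(W)
  L <- graph_laplacian(W)
  expect_lt(max(abs(rowSums(L))), 1e-12)
  expect_equal(L, diag(rowSums(W)) - W)   # elementwise oracle
  expect_error(graph_laplacian(-W), "non-negative")
})

test_that("resistance_matrix reproduces series laws and the current-flow oracle", {
  # single edge: R = 1/w
  L1 <- graph_laplacian(matrix(c(0, 4, 4, 0), 2))
  expect_equal(resistance_matrix(L1)[1, 2], 1 / 4)

  # two edges in series: R13 = 1/w1 + 1/w2
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 2; W[2, 3] <- W[3, 2] <- 5
  R <- resistance_matrix(graph_laplacian(W))
  expect_equal(R[1, 3], 1 / 2 + 1 / 5)

  # random connected graph vs unit-current linear-system oracle
  set.seed(4)
  g <- triangular_lattice(2, 3)
  w <- runif(nrow(g$edges), 0.5, 2)
  L <- graph_laplacian(migmix:::weight_matrix(g, w))
  R <- resistance_matrix(L)
  n <- nrow(L)
  for (pair in list(c(1, 4), c(2, 6), c(3, 5))) {
    b <- numeric(n); b[pair[1]] <- 1; b[pair[2]] <- -1
    v <- solve(L[-n, -n], b[-n])          # ground node n
    v <- c(v, 0)
    expect_equal(R[pair[1], pair[2]], v[pair[1]] - v[pair[2]],
                 tolerance = 1e-10)
  }
  expect_symmetric_zero_diag(R)
  expect_error(resistance_matrix(graph_laplacian(diag(0, 4))), "disconnected")
})

test_that("resistance scales as 1/k under weight scaling and obeys the triangle inequality", {
  set.seed(5)
  g <- triangular_lattice(3, 4)
  w <- runif(nrow(g$edges), 0.2, 3)
  L <- graph_laplacian(migmix:::weight_matrix(g, w))
  R <- resistance_matrix(L)
  R3 <- resistance_matrix(graph_laplacian(migmix:::weight_matrix(g, 3 * w)))
  expect_equal(R3, R / 3, tolerance = 1e-10)

  # grounded-inverse pseudo-inverse equals the dense SVD pseudo-inverse
  skip_if_not_installed("MASS")
  expect_equal(migmix:::laplacian_pinv(L), MASS::ginv(L), tolerance = 1e-8)

  n <- nrow(R)
  for (trip in replicate(20, sample(n, 3), simplify = FALSE)) {
    expect_lte(R[trip[1], trip[3]],
               R[trip[1], trip[2]] + R[trip[2], trip[3]] + 1e-12)
  }
})

test_that("observed genetic distances are mean squared frequency differences", {
  asg <- fixture_assignment(c(1, 1, 2, 2, 3))
  # identical columns across demes -> zero distance
  G0 <- matrix(1, 5, 4)
  D <- observed_genetic_distances(G0, asg)
  expect_equal(max(abs(D$D_hat)), 0)

  # all-0 vs all-2 single-sample demes -> distance 1 at every SNP
  asg2 <- fixture_assignment(c(1, 2))
  D2 <- observed_genetic_distances(rbind(rep(0, 6), rep(2, 6)), asg2)
  expect_equal(D2$D_hat[1, 2], 1)

  # elementwise oracle on a random instance
  set.seed(6)
  G <- matrix(sample(0:2, 6 * 50, TRUE), 6, 50)
  asg3 <- fixture_assignment(c(1, 1, 2, 2, 3, 3))
  D3 <- observed_genetic_distances(G, asg3)
  f <- rbind(colMeans(G[1:2, ]) / 2, colMeans(G[3:4, ]) / 2,
             colMeans(G[5:6, ]) / 2)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(D3$D_hat[i, j], mean((f[i, ] - f[j, ])^2))
  expect_symmetric_zero_diag(D3$D_hat)

  # missing genotypes error by name unless imputation is on
  G[2, 7] <- NA
  expect_error(observed_genetic_distances(G, asg3), "sample 2 at locus 7")
  expect_silent(observed_genetic_distances(G, asg3, impute = TRUE))
})

test_that("grid TSV round-trip preserves nodes and edges", {
  g <- triangular_lattice(3, 3)
  nf <- tempfile(fileext = ".tsv"); ef <- tempfile(fileext = ".tsv")
  write_grid(g, nf, ef)
  g2 <- read_grid(nf, ef)
  expect_equal(unname(g2$node_coords), unname(g$node_coords))
  expect_equal(g2$edges, g$edges)
})
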