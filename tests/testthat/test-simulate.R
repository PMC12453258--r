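# Synthetic data: Wishart draws and the stepping-stone coalescent generator.

test_that("simulate_wishart is deterministic, unbiased at large p, and honours c = 0", {
  s <- fixture_surface(o = 6, seed = 91)
  D1 <- simulate_wishart(s, p = 2000, seed = 5)
  D2 <- simulate_wishart(s, p = 2000, seed = 5)
  D3 <- simulate_wishart(s, p = 2000, seed = 6)
  expect_identical(D1, D2)
  expect_gt(max(abs(D1 - D3)), 0)
  expect_symmetric_zero_diag(D1)

  # a c = 0 edge leaves the generating distribution untouched
  e0 <- list(source = s$demes[1], dest = s$demes[3], c = 0)
  expect_equal(simulate_wishart(s, edge = e0, p = 2000, seed = 5), D1)

  # law of large numbers: entries approach the expected distances
  Dbig <- simulate_wishart(s, p = 1e6, seed = 7)
  Delta <- expected_distances(s)
  rel <- abs(Dbig - Delta)[upper.tri(Delta)] / Delta[upper.tri(Delta)]
  expect_lt(max(rel), 0.01)
})

test_that("the coalescent generator matches the island-model closed form", {
  # two demes exchanging migrants: Hudson FST = 1 / (1 + 8 Nm)
  edges <- matrix(c(1, 2), 1, 2)
  for (Nm in c(0.25, 1)) {
    fst <- sapply(1:3, function(seed) {
      set.seed(seed)
      G <- migmix:::.sim_coalescent_snps(2, edges, Nm, c(500, 500),
                                         rep(1:2, each = 40), 800,
                                         matrix(numeric(0), 0, 4))
      hudson_fst(G, rep(1:2, each = 40))[1, 2]
    })
    expect_equal(mean(fst), 1 / (1 + 8 * Nm), tolerance = 0.12)
  }
})

test_that("coalescent simulations are seed-deterministic and a c = 0 pulse is a no-op", {
  spec <- scenario_spec(grid_shape = c(3, 4), barrier_cols = NULL,
                        pulse = list(source = 1, dest = 12, c = 0, tau = 1),
                        n_snps = 60, sampling = "dense", seed = 3)
  s1 <- simulate_coalescent_grid(spec)
  s2 <- simulate_coalescent_grid(spec)
  expect_identical(s1$genotypes, s2$genotypes)
  spec$pulse <- NULL
  spec$pulse <- list(source = 1, dest = 12, c = 0, tau = 1)
  expect_identical(simulate_coalescent_grid(spec)$genotypes, s1$genotypes)
  expect_true(all(colSums(s1$genotypes) > 0))    # every SNP segregates
})

test_that("isolation by distance emerges on a uniform barrier-free lattice", {
  rhos <- sapply(1:5, function(seed) {
    spec <- scenario_spec(grid_shape = c(4, 6), barrier_cols = NULL,
                          Nm_corridor = 0.5,
                          pulse = list(source = 1, dest = 24, c = 0, tau = 1),
                          n_snps = 300, sampling = "dense", seed = seed)
    sim <- simulate_coalescent_grid(spec)
    fst <- hudson_fst(sim$genotypes, sim$sample_demes)
    demes <- as.integer(rownames(fst))
    dgeo <- as.matrix(dist(sim$grid$node_coords[demes, ]))
    ut <- upper.tri(dgeo)
    cor(dgeo[ut], fst[ut], method = "spearman")
  })
  expect_true(all(rhos > 0))
})

test_that("sampling schemes honour their published design", {
  g <- triangular_lattice(8, 12)
  truth <- list(source = 39, dest = 46)
  dn <- sampling_scheme("dense", g, truth, seed = 9)
  expect_equal(sum(dn$counts > 0), 48)             # 50% of demes
  expect_true(all(dn$counts[dn$counts > 0] == 10))
  expect_gt(dn$counts[truth$source], 0)            # source sampled
  expect_true(all(dn$deme_sizes == 1000))

  sp <- sampling_scheme("sparse", g, truth, seed = 9)
  expect_equal(sum(sp$counts > 0), 14)             # 15% of demes
  expect_equal(sp$counts[truth$source], 0)         # source unsampled
  expect_gt(sp$counts[truth$dest], 0)
  expect_true(all(sp$counts[sp$counts > 0] %in% 1:10))
  expect_true(all(sp$deme_sizes >= 100 & sp$deme_sizes <= 10000))

  expect_identical(sampling_scheme("sparse", g, truth, seed = 9), sp)
})

test_that("the mass-migration pulse pulls the destination toward the source", {
  # small lattice, strong pulse: destination deme's distance to the source
  # side drops relative to the no-pulse simulation
  base_spec <- scenario_spec(grid_shape = c(3, 6), barrier_cols = NULL,
                             Nm_corridor = 0.2,
                             pulse = list(source = 8, dest = 11, c = 0,
                                          tau = 1),
                             n_snps = 400, sampling = "dense", seed = 21)
  pulse_spec <- base_spec
  pulse_spec$pulse$c <- 0.6
  f0 <- hudson_fst(simulate_coalescent_grid(base_spec)$genotypes,
                   simulate_coalescent_grid(base_spec)$sample_demes)
  sim1 <- simulate_coalescent_grid(pulse_spec)
  f1 <- hudson_fst(sim1$genotypes, sim1$sample_demes)
  expect_lt(f1["8", "11"], f0["8", "11"] * 0.6)
})
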