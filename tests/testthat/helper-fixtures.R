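# Shared fixtures: small grids, surfaces and assignments built in code.

fixture_surface <- function(nrow = 4, ncol = 5, o = 8, seed = 2,
                            q_mean = 0.3) {
  set.seed(seed)
  g <- triangular_lattice(nrow, ncol)
  n <- nrow(g$node_coords)
  demes <- sort(sample(n, o))
  w <- exp(stats::rnorm(nrow(g$edges), 0, 0.3))
  q <- exp(stats::rnorm(o, log(q_mean), 0.2))
  migmix:::new_migration_surface(g, demes, w, q, 1, 1)
}

fixture_assignment <- function(demes) {
  obs <- sort(unique(demes))
  structure(list(deme_of_sample = demes, observed_demes = obs,
                 counts = as.integer(table(factor(demes, levels = obs)))),
            class = "sample_assignment")
}

# assignment + distance bundle from a coalescent simulation
sim_to_inputs <- function(sim) {
  asg <- structure(list(deme_of_sample = sim$sample_demes,
                        observed_demes = sort(unique(sim$sample_demes)),
                        counts = as.integer(table(sim$sample_demes))),
                   class = "sample_assignment")
  list(asg = asg, bundle = observed_genetic_distances(sim$genotypes, asg))
}

expect_symmetric_zero_diag <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - t(M))), tol)
  expect_lt(max(abs(diag(M))), tol)
}
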