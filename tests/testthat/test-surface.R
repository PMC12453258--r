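# Baseline surface fitting: expected distances, penalized ML, gradients,
# cross-validation and fit summaries.

test_that("expected distances follow R + q_i + q_j", {
  # two demes: R = 2, q = (0.5, 0.5) -> Delta = 3
  g <- triangular_lattice(1, 2)
  s <- migmix:::new_migration_surface(g, c(1, 2), w = 0.5, q = c(0.5, 0.5),
                                      1, 1)
  expect_equal(expected_distances(s)[1, 2], 1 / 0.5 + 1)

  # q -> 0 limit leaves the resistance distances
  s0 <- fixture_surface(o = 5, seed = 71)
  s0$q <- rep(1e-12, 5)
  R <- resistance_matrix(graph_laplacian(
    migmix:::weight_matrix(s0$grid, s0$w)))[s0$demes, s0$demes]
  expect_equal(expected_distances(s0), R, tolerance = 1e-8)

  # elementwise oracle
  s1 <- fixture_surface(o = 4, seed = 72)
  D <- expected_distances(s1)
  Rfull <- resistance_matrix(graph_laplacian(
    migmix:::weight_matrix(s1$grid, s1$w)))
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(D[i, j],
                 Rfull[s1$demes[i], s1$demes[j]] + s1$q[i] + s1$q[j])
})

test_that("analytic gradients of the penalized objective match finite differences", {
  s <- fixture_surface(o = 6, seed = 73)
  D <- simulate_wishart(s, p = 3000, seed = 74)
  ctx <- migmix:::make_fit_context(D, s$grid, s$demes, 3000, 0.7, 1.3)
  theta <- c(log(s$w), log(s$q))
  obj <- migmix:::surface_objective(theta, ctx)
  idx <- c(1, 5, 20, length(s$w) + 2, length(s$w) + 6)
  for (i in idx) {
    h <- 1e-6
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    fd <- (migmix:::surface_objective(tp, ctx)$value -
             migmix:::surface_objective(tm, ctx)$value) / (2 * h)
    expect_equal(obj$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("the fit recovers a uniform surface and flattens under heavy smoothing", {
  set.seed(75)
  g <- triangular_lattice(4, 5)
  demes <- 1:20   # all demes observed so every edge is identified
  s_true <- migmix:::new_migration_surface(g, demes, rep(1.5, nrow(g$edges)),
                                           rep(0.3, 20), 1, 1)
  D <- simulate_wishart(s_true, p = 2e5, seed = 76)
  asg <- fixture_assignment(demes)
  fit <- fit_baseline(D, g, asg, lambda_w = 1, lambda_q = 1, p = 2e5)
  w <- fit$surface$w
  expect_lt(sd(w) / mean(w), 0.05)      # coefficient of variation
  expect_true(fit$diagnostics$converged)

  # penalty-dominated limit: weights collapse to a single shared value
  fit_big <- fit_baseline(D, g, asg, lambda_w = 1e6, lambda_q = 1, p = 2e5)
  expect_lt(max(fit_big$surface$w) / min(fit_big$surface$w), 1 + 1e-3)

  # final penalized objective is no worse than the initialization's
  ci <- migmix:::constant_init(D, g, demes, 2e5)
  ctx <- migmix:::make_fit_context(D, g, demes, 2e5, 1, 1)
  nll_init <- migmix:::surface_objective(
    c(rep(ci$log_w, nrow(g$edges)), rep(ci$log_q, 20)), ctx)$value
  expect_lte(fit$diagnostics$nll, nll_init)
})

test_that("near-constant observed distances yield a near-flat fitted surface", {
  set.seed(77)
  g <- triangular_lattice(3, 4)
  demes <- 1:12
  o <- 12
  D <- matrix(0.5, o, o) + matrix(rnorm(o * o, 0, 0.002), o)
  D <- (D + t(D)) / 2; diag(D) <- 0
  fit <- fit_baseline(D, g, fixture_assignment(demes), 1, 1, p = 1000)
  w <- fit$surface$w
  expect_lt(max(w) / min(w), 1.6)
})

test_that("fitted q correlates with the generating variances across replicates", {
  set.seed(78)
  g <- triangular_lattice(8, 12)
  demes <- sort(sample(96, 20))
  cors <- sapply(1:10, function(k) {
    q_true <- exp(rnorm(20, log(0.3), 0.35))
    s_true <- migmix:::new_migration_surface(g, demes, rep(1, nrow(g$edges)),
                                             q_true, 1, 1)
    D <- simulate_wishart(s_true, p = 1000, seed = 100 + k)
    fit <- fit_baseline(D, g, fixture_assignment(demes), 1, 0.1, p = 1000,
                        maxit = 400)
    cor(fit$surface$q, q_true)
  })
  expect_gt(mean(cors > 0.8), 0.9)
})

test_that("model_r_squared is a squared correlation of upper triangles", {
  set.seed(79)
  D <- matrix(runif(36), 6); D <- (D + t(D)) / 2; diag(D) <- 0
  expect_equal(model_r_squared(D, D), 1)
  expect_equal(model_r_squared(D, 2 * D + 1), 1)     # affine invariance
  F2 <- matrix(runif(36), 6); F2 <- (F2 + t(F2)) / 2; diag(F2) <- 0
  expect_equal(model_r_squared(D, F2),
               cor(D[upper.tri(D)], F2[upper.tri(F2)])^2)
  expect_error(model_r_squared(D, matrix(1, 6, 6) - diag(1, 6)), "undefined")
})

test_that("cross-validation is a leave-one-deme-out partition and honours degenerate grids", {
  s <- fixture_surface(o = 6, seed = 80)
  D <- simulate_wishart(s, p = 2000, seed = 81)
  asg <- fixture_assignment(s$demes)
  cv <- cross_validate(D, s$grid, asg, lambda_grid = 0.7,
                       lambda_q_grid = 1.3, p = 2000, maxit = 150)
  expect_equal(cv$lambda_cv, 0.7)
  expect_equal(cv$lambda_q_cv, 1.3)
  expect_equal(nrow(cv$cv_table), 1)

  cv2 <- cross_validate(D, s$grid, asg, lambda_grid = c(0.5, 5),
                        lambda_q_grid = 1, p = 2000, maxit = 150)
  expect_true(cv2$lambda_cv %in% c(0.5, 5))
  expect_true(all(is.finite(cv2$cv_table$error)))
})
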