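# Variogram fitting, kriging of deme variances, and the long-range-edge
# likelihood.

test_that("the exponential variogram has the right limits and recovers known parameters", {
  set.seed(61)
  o <- 30
  # domain much wider than the range so the empirical variogram resolves the
  # sill from many effectively independent patches
  R <- as.matrix(dist(matrix(runif(o * 2, 0, 40), o)))
  b <- 0.05; C0 <- 0.4; a <- 1.2
  vg_true <- function(r) b + C0 * (1 - exp(-r / a))
  # build q with semivariance structure matching the model: Gaussian field
  # with covariance C0 exp(-r/a) plus nugget noise
  Sig <- C0 * exp(-R / a) + diag(b, o)
  ch <- chol(Sig + diag(1e-8, o))
  sills <- sapply(1:5, function(k) {
    q <- drop(t(ch) %*% rnorm(o)) + 3
    vg <- fit_variogram(q, R)
    expect_false(vg$degenerate)
    # nugget at zero distance, sill in the far field
    expect_equal(migmix:::variogram_value(vg, 0), vg$b)
    expect_equal(migmix:::variogram_value(vg, 1e9), vg$b + vg$C0)
    vg$b + vg$C0
  })
  # recovered total sill within 20% of the truth (median over field draws)
  expect_lt(abs(median(sills) - (b + C0)) / (b + C0), 0.2)

  # all-equal variances flag the degenerate branch
  vg0 <- fit_variogram(rep(0.4, 10), R[1:10, 1:10])
  expect_true(vg0$degenerate)
  expect_equal(vg0$b, 0); expect_equal(vg0$C0, 0)
  expect_error(fit_variogram(1:3, R[1:3, 1:3]), "at least 4")
})

test_that("ordinary kriging reproduces constant fields and respects symmetry", {
  set.seed(62)
  o <- 12
  R <- as.matrix(dist(matrix(runif(o * 2, 0, 3), o)))
  q <- runif(o, 0.2, 0.8)
  vg <- fit_variogram(q, R)
  # constant field: weights sum to 1 forces exact reproduction
  qc <- rep(0.37, o)
  expect_equal(krige_variance(vg, runif(o, 0.1, 2), qc), 0.37)
  kw <- krige_variance(vg, R[1, ], q, return_weights = TRUE)
  expect_equal(sum(kw$weights), 1, tolerance = 1e-8)

  # two equidistant demes, all others far beyond the range: weights ~ 1/2 each
  R2 <- matrix(5000, 6, 6); diag(R2) <- 0
  R2[1, 2] <- R2[2, 1] <- 0.02   # target sits midway between demes 1 and 2
  q2 <- c(0.3, 0.5, 5, 5, 5, 5)
  vg2 <- structure(list(b = 0, C0 = 1, a = 1, degenerate = FALSE,
                        R_obs = R2, bins = NULL), class = "variogram_model")
  kw2 <- krige_variance(vg2, c(0.01, 0.01, 5000, 5000, 5000, 5000), q2,
                        return_weights = TRUE)
  expect_equal(kw2$weights[1], kw2$weights[2], tolerance = 1e-6)
  expect_equal(kw2$q, mean(q2[1:2]), tolerance = 0.05)
})

test_that("kriged variances track a smooth spatial field at held-out demes", {
  set.seed(63)
  o <- 20
  xy <- matrix(runif(o * 2, 0, 3), o)
  R <- as.matrix(dist(xy))
  q <- 0.5 + 0.3 * sin(xy[, 1]) + 0.2 * cos(xy[, 2]) +
    rnorm(o, 0, 0.02)
  pred <- numeric(o)
  for (h in seq_len(o)) {
    vg <- fit_variogram(q[-h], R[-h, -h])
    pred[h] <- krige_variance(vg, R[h, -h], q[-h])
  }
  expect_gt(cor(pred, q), 0.7)
})

test_that("the edge likelihood reduces to baseline at c = 0 and recovers the source fraction", {
  s <- fixture_surface(o = 8, seed = 64)
  D <- simulate_wishart(s, p = 2000, seed = 65)
  base <- wishart_nll(D, expected_distances(s), 2000)
  e0 <- list(source = s$demes[1], dest = s$demes[4], c = 0)
  expect_equal(lre_nll(D, s, e0, 2000), base, tolerance = 1e-10)

  # recovery at p = 1e5: the maximizing c sits within 0.05 of the truth
  truth <- list(source = s$demes[2], dest = s$demes[6], c = 0.5)
  D2 <- simulate_wishart(s, edge = truth, p = 1e5, seed = 66)
  ctx <- migmix:::lre_context(D2, s, 1e5)
  op <- migmix:::optimize_c(ctx, truth$source, truth$dest)
  expect_lt(abs(op$c - 0.5), 0.05)

  # grid scan agrees with the scalar optimizer and is unimodal around it
  cs <- seq(0, 1, by = 0.001)
  nlls <- vapply(cs, function(cc)
    migmix:::context_nll(ctx, truth$source, truth$dest, cc), numeric(1))
  expect_lt(abs(cs[which.min(nlls)] - op$c), 0.002)
  sgn <- diff(nlls) > 0
  expect_lte(sum(diff(sgn) != 0), 1)   # one sign change: unimodal profile
})

test_that("profile likelihood contains the MLE and sharpens with more SNPs", {
  s <- fixture_surface(o = 8, seed = 67)
  truth <- list(source = s$demes[3], dest = s$demes[7], c = 0.4)
  widths <- sapply(c(1000, 100000), function(p) {
    D <- simulate_wishart(s, edge = truth, p = p, seed = 68)
    edge <- list(source = truth$source, dest = truth$dest)
    pr <- profile_likelihood_c(edge, D, s, p)
    expect_gte(pr$c_hat, pr$interval[1])
    expect_lte(pr$c_hat, pr$interval[2])
    expect_equal(pr$c[which.max(pr$loglik)], pr$c_hat)
    diff(pr$interval)
  })
  expect_lt(widths[2], widths[1])
})
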