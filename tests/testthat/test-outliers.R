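# Deviation statistics, outlier flagging, mixture support, directionality and
# recipient ranking.

test_that("deviation statistics match a literal log-ratio computation", {
  set.seed(51)
  o <- 6
  Delta <- as.matrix(dist(matrix(runif(o * 2), o))) + 0.5
  diag(Delta) <- 0
  D <- Delta * exp(matrix(rnorm(o * o, 0, 0.1), o))
  D <- (D + t(D)) / 2; diag(D) <- 0
  dev <- deviation_statistics(D, Delta)
  raw <- c()
  for (i in 1:(o - 1)) for (j in (i + 1):o) raw <- c(raw, log(D[i, j] / Delta[i, j]))
  expect_equal(dev$raw, raw)
  expect_equal(dev$x, (raw - mean(raw)) / sd(raw))
  expect_equal(mean(dev$x), 0, tolerance = 1e-12)
  expect_equal(sd(dev$x), 1, tolerance = 1e-12)

  # the pair observed at half its fitted value has the minimum deviation
  D2 <- Delta; D2[2, 5] <- D2[5, 2] <- Delta[2, 5] / 2
  D2[1, 3] <- D2[3, 1] <- Delta[1, 3] * 1.001   # avoid full degeneracy
  dev2 <- deviation_statistics(D2, Delta)
  worst <- dev2$pairs[which.min(dev2$x), ]
  expect_equal(sort(unname(worst)), c(2, 5))

  # perfect fit: degenerate flag with all-zero statistics
  dev3 <- deviation_statistics(Delta + diag(0, o), Delta)
  expect_true(dev3$degenerate)
  expect_true(all(dev3$x == 0))

  Dbad <- D; Dbad[1, 2] <- Dbad[2, 1] <- 0
  expect_error(deviation_statistics(Dbad, Delta), "pair \\(1, 2\\)")
})

test_that("flag_outliers keeps the negative 5% tail with deterministic ties", {
  set.seed(52)
  x <- rnorm(100)
  out <- flag_outliers(x, 0.05)
  expect_length(out, 5)
  expect_setequal(out, order(x)[1:5])                # sort-and-slice oracle
  # ties: all-equal x cannot be flagged (none negative); shifted negative ties
  xt <- rep(-1, 40)
  expect_equal(flag_outliers(xt, 0.1), 1:4)          # first by index
  # fewer negatives than the tail size: only negatives are returned
  xp <- c(-0.5, abs(rnorm(99)))
  expect_equal(flag_outliers(xp, 0.05), 1L)
  expect_error(flag_outliers(x, 0), "fraction")
})

test_that("mixture support separates one- and two-component residuals", {
  # null calibration: single-Normal draws rarely reach the support threshold
  set.seed(53)
  null_hits <- 0
  for (k in 1:40) {
    lr <- mixture_support(rnorm(500))
    expect_gte(as.numeric(lr), 0)
    null_hits <- null_hits + (lr > 10)
  }
  expect_lte(null_hits / 40, 0.10)

  # well-separated components always exceed it
  for (k in 1:20) {
    x <- c(rnorm(400, -3), rnorm(100, 3))
    expect_gt(as.numeric(mixture_support(x)), 10)
  }
  expect_error(mixture_support(rnorm(5)), "at least 10")
})

test_that("hand-rolled EM agrees with the mclust oracle on mixed data", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  set.seed(54)
  x <- c(rnorm(300, -1.5, 0.7), rnorm(200, 1.5, 0.7))
  fit <- migmix:::em_norm2(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("direction resolution returns both demes for symmetric data", {
  s <- fixture_surface(o = 6, seed = 55)
  # make the configuration exactly symmetric in demes 1 and 2 of the surface
  D <- expected_distances(s)
  i <- s$demes[1]; j <- s$demes[2]
  D[1, ] <- D[2, ]; D[, 1] <- D[, 2]
  D[1, 2] <- D[2, 1] <- expected_distances(s)[1, 2]
  D <- (D + t(D)) / 2; diag(D) <- 0
  sym <- resolve_direction(c(i, j), D, s, 2000)
  expect_setequal(sym, c(i, j))
})

test_that("direction resolution recovers the simulated recipient", {
  s <- fixture_surface(o = 6, seed = 56)
  i <- s$demes[2]; j <- s$demes[5]
  hits <- 0
  for (seed in 1:10) {
    D <- simulate_wishart(s, edge = list(source = i, dest = j, c = 0.5),
                          p = 10000, seed = seed)
    r <- resolve_direction(c(i, j), D, s, 10000)
    hits <- hits + identical(r, j)
  }
  expect_gte(hits, 8)
})

test_that("recipient ranking follows the weighted-sum statistic", {
  # deme A in three outlier pairs beats deme B in one, at equal deviations
  dev <- list(pairs = rbind(c(1, 2), c(1, 3), c(1, 4), c(5, 6)),
              x = c(-2, -2, -2, -2))
  class(dev) <- "deviation_set"
  rk <- rank_recipients(1:4, dev, recipients = list(1, 1, 1, 5))
  expect_equal(rk$deme[1], 1)
  expect_equal(rk$f[1], 3 * (-2 * exp(2)))
  expect_equal(rk$f[rk$deme == 5], -2 * exp(2))

  # literal formula oracle on a random instance, unfiltered mode
  set.seed(57)
  pairs <- t(combn(5, 2))
  x <- rnorm(nrow(pairs))
  dev2 <- structure(list(pairs = pairs, x = x), class = "deviation_set")
  out <- seq_len(nrow(pairs))
  rk2 <- rank_recipients(out, dev2, recipients = NULL,
                         filter_by_direction = FALSE)
  f_oracle <- sapply(1:5, function(d) {
    idx <- which(pairs[, 1] == d | pairs[, 2] == d)
    sum(x[idx] * exp(-x[idx]))
  })
  expect_equal(rk2$f[match(1:5, rk2$deme)], f_oracle)
  expect_equal(rk2$deme, (1:5)[order(f_oracle, 1:5)])

  # single outlier pair with a unique recipient ranks that deme first
  rk3 <- rank_recipients(1, dev2, recipients = list(3))
  expect_equal(rk3$deme, 3)
})
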