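# Residual outlier detection: pairs of demes more genetically similar than
# the fitted surface predicts, support for two-component structure in the
# residuals, directionality of candidate gene flow, and recipient ranking.

#' Pairwise deviation statistics
#'
#' The deviation for a deme pair is the centered and standardized log-ratio of
#' observed to fitted genetic distance over all upper-triangle pairs; large
#' negative values flag pairs that are unexpectedly similar.
#'
#' @param D_hat,Delta_fitted matched o x o matrices with strictly positive
#'   off-diagonal entries.
#' @return A `deviation_set`: list with `pairs` (n_pairs x 2 matrix of deme
#'   indices, upper-triangle order), `x` (standardized deviations),
#'   `raw` (log-ratios) and `degenerate` (TRUE when all ratios coincide, in
#'   which case `x` is all zeros).
#' @export
deviation_statistics <- function(D_hat, Delta_fitted) {
  o <- nrow(D_hat)
  ut <- which(upper.tri(D_hat), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
  obs <- D_hat[ut]; fit <- Delta_fitted[ut]
  bad <- which(obs <= 0 | fit <= 0)
  if (length(bad))
    stop(sprintf("non-positive distance for deme pair (%d, %d)",
                 ut[bad[1], 1], ut[bad[1], 2]))
  raw <- log(obs / fit)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0) {
    x <- rep(0, length(raw)); degenerate <- TRUE
  } else {
    x <- (raw - mean(raw)) / s; degenerate <- FALSE
  }
  structure(list(pairs = ut, x = x, raw = raw, degenerate = degenerate),
            class = "deviation_set")
}

#' Flag candidate outlier pairs
#'
#' The `ceil(fraction * n_pairs)` pairs with the most negative deviations,
#' restricted to the negative tail; ties broken by pair index.
#'
#' @param x deviations (vector, or a `deviation_set`).
#' @param fraction tail fraction, default 0.05.
#' @return integer indices into the pair list.
#' @export
flag_outliers <- function(x, fraction = 0.05) {
  if (inherits(x, "deviation_set")) x <- x$x
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  k <- ceiling(fraction * length(x))
  ord <- order(x, seq_along(x))
  top <- ord[seq_len(k)]
  top[x[top] < 0]
}

# Closed-form single-Normal maximized log-likelihood.
norm1_loglik <- function(x) {
  n <- length(x)
  s2 <- mean((x - mean(x))^2)
  if (s2 <= 0) return(Inf)
  -n / 2 * (log(2 * pi * s2) + 1)
}

# 1-D two-component Gaussian mixture by EM. Deterministic: k-means
# initialisation under a locally fixed seed plus jittered restarts; component
# variances floored to avoid degenerate spikes.
em_norm2 <- function(x, restarts = 5, maxit = 500, tol = 1e-10, seed = 0) {
  n <- length(x)
  floor_var <- max(1e-6 * stats::var(x), 1e-12)
  run_em <- function(mu, s2, pi1) {
    ll_old <- -Inf
    for (it in seq_len(maxit)) {
      d1 <- pi1 * stats::dnorm(x, mu[1], sqrt(s2[1]))
      d2 <- (1 - pi1) * stats::dnorm(x, mu[2], sqrt(s2[2]))
      tot <- d1 + d2
      tot[tot < 1e-300] <- 1e-300
      r <- d1 / tot
      ll <- sum(log(tot))
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
      n1 <- sum(r); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
      s2 <- c(max(sum(r * (x - mu[1])^2) / n1, floor_var),
              max(sum((1 - r) * (x - mu[2])^2) / n2, floor_var))
      pi1 <- n1 / n
    }
    list(loglik = ll, mu = mu, s2 = s2, pi1 = pi1)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  best <- NULL
  km <- tryCatch(stats::kmeans(x, 2, nstart = 3), error = function(e) NULL)
  inits <- list()
  if (!is.null(km)) {
    mu0 <- as.numeric(km$centers)
    s20 <- vapply(1:2, function(k) {
      v <- stats::var(x[km$cluster == k])
      if (!is.finite(v) || v <= 0) floor_var else v
    }, numeric(1))
    inits[[1]] <- list(mu = mu0, s2 = s20, pi1 = mean(km$cluster == 1))
  }
  qs <- stats::quantile(x, c(0.1, 0.9))
  inits[[length(inits) + 1]] <- list(mu = as.numeric(qs),
                                     s2 = rep(stats::var(x), 2), pi1 = 0.5)
  while (length(inits) < restarts) {
    inits[[length(inits) + 1]] <- list(
      mu = sort(stats::rnorm(2, mean(x), stats::sd(x))),
      s2 = rep(stats::var(x) * stats::runif(1, 0.2, 1), 2),
      pi1 = stats::runif(1, 0.2, 0.8))
  }
  for (init in inits) {
    fit <- tryCatch(run_em(init$mu, pmax(init$s2, floor_var), init$pi1),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  best
}

#' Mixture support statistic L_r
#'
#' `L_r = -2 ln(L1 / L2)` where L1 is the maximized likelihood of the
#' deviations under a single Normal and L2 under a two-component Normal
#' mixture; floored at zero. Values above 10 are read as substantial support
#' for two-component structure in the residuals (hence for a long-range edge).
#'
#' @param x deviations (vector or `deviation_set`).
#' @return scalar L_r with attribute `mixture` holding the two-component fit.
#' @export
mixture_support <- function(x) {
  if (inherits(x, "deviation_set")) x <- x$x
  if (length(x) < 10) stop("mixture support needs at least 10 pairs")
  ll1 <- norm1_loglik(x)
  if (!is.finite(ll1)) return(structure(0, mixture = NULL))
  fit2 <- em_norm2(x)
  lr <- max(0, 2 * (fit2$loglik - ll1))
  structure(lr, mixture = fit2)
}

#' Resolve the direction of gene flow for an outlier pair
#'
#' Fits a pulse in both directions (source fraction free, all surface
#' parameters at their baseline values). If the i-to-j fit is more than 2
#' log-likelihood units better than j-to-i, j is the putative recipient (and
#' vice versa); within 2 units both demes are returned.
#'
#' @param pair length-2 vector of observed deme ids (grid node ids).
#' @param D_hat,surface,p as elsewhere.
#' @param prior_events earlier edges kept in the model.
#' @param ctx optional prebuilt scan context (internal reuse).
#' @return vector of putative recipient deme ids (subset of the pair).
#' @export
resolve_direction <- function(pair, D_hat, surface, p, prior_events = list(),
                              ctx = NULL) {
  i <- pair[1]; j <- pair[2]
  if (i == j) stop("pair must contain two distinct demes")
  if (is.null(ctx)) ctx <- lre_context(D_hat, surface, p, prior_events)
  ll_ij <- -optimize_c(ctx, i, j)$nll   # i -> j : j recipient
  ll_ji <- -optimize_c(ctx, j, i)$nll
  d <- ll_ij - ll_ji
  if (d > 2) j else if (d < -2) i else c(i, j)
}

#' Rank putative recipient demes
#'
#' The weighted-sum statistic `f_i = sum_j x_ij exp(-x_ij)` over outlier
#' pairs in which deme i is a putative recipient; demes are ordered most
#' negative first (ties by deme id). Multiple strongly negative pairs push a
#' deme up the ranking.
#'
#' @param outlier_pairs indices into the deviation pair list.
#' @param dev a `deviation_set`.
#' @param recipients list (parallel to `outlier_pairs`) of putative recipient
#'   deme indices for each pair, from [resolve_direction()].
#' @param filter_by_direction if FALSE, f_i sums over all outlier pairs
#'   involving i regardless of direction calls.
#' @return A `recipient_ranking`: data frame (deme, f) ordered by f.
#' @export
rank_recipients <- function(outlier_pairs, dev, recipients,
                            filter_by_direction = TRUE) {
  if (!length(outlier_pairs)) stop("no outlier pairs to rank")
  f <- list()
  for (k in seq_along(outlier_pairs)) {
    idx <- outlier_pairs[k]
    x <- dev$x[idx]
    demes <- dev$pairs[idx, ]
    targets <- if (filter_by_direction) recipients[[k]] else demes
    for (d in targets) {
      key <- as.character(d)
      f[[key]] <- (if (is.null(f[[key]])) 0 else f[[key]]) + x * exp(-x)
    }
  }
  out <- data.frame(deme = as.integer(names(f)), f = unlist(f, use.names = FALSE))
  out <- out[order(out$f, out$deme), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("recipient_ranking", "data.frame")
  out
}
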