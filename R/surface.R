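# Baseline effective migration surface: per-edge weights W and per-deme
# variances q, fitted by penalized Wishart maximum likelihood with analytic
# gradients in log-parameters.

new_migration_surface <- function(grid, demes, w, q, lambda_w, lambda_q) {
  structure(list(grid = grid, demes = demes, w = w, q = q,
                 lambda_w = lambda_w, lambda_q = lambda_q),
            class = "migration_surface")
}

#' @export
print.migration_surface <- function(x, ...) {
  cat("migration_surface:", length(x$w), "edges,", length(x$demes),
      "observed demes\n")
  cat(sprintf("  weights: [%.3g, %.3g]  q: [%.3g, %.3g]  lambda = %.3g, lambda_q = %.3g\n",
              min(x$w), max(x$w), min(x$q), max(x$q), x$lambda_w, x$lambda_q))
  invisible(x)
}

# Pseudo-inverse of the surface Laplacian over all grid nodes.
surface_pinv <- function(surface) {
  L <- graph_laplacian(weight_matrix(surface$grid, surface$w))
  laplacian_pinv(L)
}

#' Expected genetic distances under a fitted surface
#'
#' Delta_ij = R_ij + q_i + q_j over the observed demes, where R is the
#' resistance distance on the weighted grid.
#'
#' @param surface a `migration_surface`.
#' @param demes node ids to evaluate at; defaults to the surface's observed
#'   demes. Variances for unsampled nodes must be supplied via `q_extra`.
#' @param q_extra named vector of variances for nodes outside the observed set.
#' @return symmetric matrix with zero diagonal.
#' @export
expected_distances <- function(surface, demes = surface$demes, q_extra = NULL) {
  Lp <- surface_pinv(surface)
  dLp <- diag(Lp)
  R <- outer(dLp[demes], dLp[demes], "+") - 2 * Lp[demes, demes, drop = FALSE]
  q <- numeric(length(demes))
  obs <- match(demes, surface$demes)
  q[!is.na(obs)] <- surface$q[obs[!is.na(obs)]]
  if (any(is.na(obs))) {
    if (is.null(q_extra)) stop("variances needed for unsampled nodes; supply q_extra")
    q[is.na(obs)] <- q_extra[as.character(demes[is.na(obs)])]
  }
  Delta <- R + outer(q, q, "+")
  diag(Delta) <- 0
  Delta
}

# Edge pairs sharing a node, for the smoothness penalty on log-weights.
edge_pair_index <- function(grid) {
  m <- nrow(grid$edges)
  by_node <- vector("list", nrow(grid$node_coords))
  for (e in seq_len(m)) {
    a <- grid$edges[e, 1]; b <- grid$edges[e, 2]
    by_node[[a]] <- c(by_node[[a]], e)
    by_node[[b]] <- c(by_node[[b]], e)
  }
  pairs <- do.call(rbind, lapply(by_node, function(es) {
    if (length(es) < 2) return(NULL)
    t(utils::combn(es, 2))
  }))
  pairs
}

# Objective + gradient over theta = (log w, log q_observed[, c_last]), with
# optional long-range events. Events: list of list(source, dest, c, gamma) in
# grid-node ids; gamma are kriging weights over observed demes for an
# unsampled source (NULL when the source is observed). When ctx$free_c is
# TRUE the last event's source fraction is the final entry of theta and its
# partial derivative is returned with the gradient.
surface_objective <- function(theta, ctx) {
  me <- ctx$n_edges
  w <- exp(theta[seq_len(me)])
  lq <- theta[me + seq_len(ctx$o)]
  q <- exp(lq)
  if (isTRUE(ctx$free_c) && length(ctx$events))
    ctx$events[[length(ctx$events)]]$c <-
      min(max(theta[me + ctx$o + 1], 0), 1)

  L <- graph_laplacian(weight_matrix(ctx$grid, w))
  Lp <- laplacian_pinv(L)
  V <- ctx$nodesV
  dLp <- diag(Lp)
  R_V <- outer(dLp[V], dLp[V], "+") - 2 * Lp[V, V, drop = FALSE]
  diag(R_V) <- 0

  q_V <- numeric(length(V))
  q_V[ctx$obs_in_V] <- q
  for (ev in ctx$events) {
    if (!is.null(ev$gamma)) q_V[match(ev$source, V)] <- sum(ev$gamma * q)
  }
  q_V <- pmax(q_V, 1e-8)

  if (length(ctx$events)) {
    T <- coal_times_from_Rq(R_V, q_V)
    T_in <- vector("list", length(ctx$events))
    for (k in seq_along(ctx$events)) {
      ev <- ctx$events[[k]]
      T_in[[k]] <- T
      T <- post_event_coal_times(T, match(ev$source, V), match(ev$dest, V), ev$c)
    }
    Delta <- delta_from_coal_times(T)[ctx$obs_in_V, ctx$obs_in_V, drop = FALSE]
  } else {
    Delta <- R_V + outer(q_V, q_V, "+")
    diag(Delta) <- 0
  }

  lik <- wishart_nll_core(ctx$wctx, Delta, grad = TRUE)
  G <- lik$G_pair

  # penalties on log-parameters
  dpen_w <- numeric(me); dpen_q <- numeric(ctx$o)
  pen <- 0
  if (ctx$lambda_w > 0 && !is.null(ctx$edge_pairs)) {
    dif <- theta[ctx$edge_pairs[, 1]] - theta[ctx$edge_pairs[, 2]]
    pen <- pen + ctx$lambda_w * sum(dif^2)
    g <- 2 * ctx$lambda_w * dif
    s1 <- rowsum(g, ctx$edge_pairs[, 1])
    s2 <- rowsum(g, ctx$edge_pairs[, 2])
    dpen_w[as.integer(rownames(s1))] <- dpen_w[as.integer(rownames(s1))] + s1[, 1]
    dpen_w[as.integer(rownames(s2))] <- dpen_w[as.integer(rownames(s2))] - s2[, 1]
  }
  if (ctx$lambda_q > 0) {
    cen <- lq - mean(lq)
    pen <- pen + ctx$lambda_q * sum(cen^2)
    dpen_q <- 2 * ctx$lambda_q * cen   # centering projector is idempotent
  }

  # gradient wrt T' (independent-parameter convention, symmetric storage)
  nV <- length(V)
  M <- matrix(0, nV, nV)
  M[ctx$obs_in_V, ctx$obs_in_V] <- 4 * G
  diag(M)[ctx$obs_in_V] <- -rowSums(G)
  dc_free <- NULL
  for (k in rev(seq_along(ctx$events))) {
    ev <- ctx$events[[k]]
    si <- match(ev$source, V); di <- match(ev$dest, V)
    if (isTRUE(ctx$free_c) && k == length(ctx$events)) {
      # d nll / d c of the last event, using the adjoint at this stage and
      # the forward input T of the event
      Ti <- T_in[[k]]; cc <- ev$c
      kk <- setdiff(seq_len(nV), c(si, di))
      dc_free <- sum(M[kk, di] * (Ti[si, kk] - Ti[kk, di])) +
        M[si, di] * (Ti[si, si] - Ti[si, di]) +
        M[di, di] * (-2 * (1 - cc) * Ti[di, di] +
                       (2 - 4 * cc) * Ti[si, di] + 2 * cc * Ti[si, si])
    }
    M <- event_adjoint(M, si, di, ev$c)
  }

  dq_V <- diag(M) + (rowSums(M) - diag(M)) / 2
  gp_V <- M / 4
  diag(gp_V) <- 0

  dq <- dq_V[ctx$obs_in_V]
  for (ev in ctx$events) {
    if (!is.null(ev$gamma)) dq <- dq + ev$gamma * dq_V[match(ev$source, V)]
  }

  n <- nrow(Lp)
  gp <- matrix(0, n, n)
  gp[V, V] <- gp_V
  H <- diag(rowSums(gp)) - gp
  K <- -Lp %*% H %*% Lp
  a <- ctx$grid$edges[, 1]; b <- ctx$grid$edges[, 2]
  dw <- (K[cbind(a, a)] + K[cbind(b, b)] - 2 * K[cbind(a, b)]) * w

  grad <- c(dw + dpen_w, dq * q + dpen_q)
  if (isTRUE(ctx$free_c)) grad <- c(grad, dc_free)
  list(value = lik$nll + pen, grad = grad, nll = lik$nll)
}

make_fit_context <- function(D_hat, grid, demes, p, lambda_w, lambda_q,
                             events = list()) {
  sources <- unlist(lapply(events, `[[`, "source"))
  nodesV <- sort(unique(c(demes, sources, unlist(lapply(events, `[[`, "dest")))))
  list(grid = grid, demes = demes, o = length(demes),
       n_edges = nrow(grid$edges),
       nodesV = nodesV, obs_in_V = match(demes, nodesV),
       events = events,
       lambda_w = lambda_w, lambda_q = lambda_q,
       edge_pairs = if (lambda_w > 0) edge_pair_index(grid) else NULL,
       wctx = wishart_context(D_hat, p))
}

# Constant-weight, constant-variance starting values: 2-parameter fit reusing
# a unit-weight resistance matrix (R scales as 1/w).
constant_init <- function(D_hat, grid, demes, p) {
  L1 <- graph_laplacian(weight_matrix(grid, rep(1, nrow(grid$edges))))
  R1 <- resistance_matrix(L1)[demes, demes, drop = FALSE]
  wctx <- wishart_context(D_hat, p)
  f <- function(par) {
    R <- R1 / exp(par[1])
    Delta <- R + 2 * exp(par[2])
    diag(Delta) <- 0
    tryCatch(wishart_nll_core(wctx, Delta)$nll, error = function(e) 1e12)
  }
  q0 <- max(mean(D_hat[upper.tri(D_hat)]) / 4, 1e-6)
  w0 <- max(mean(R1[upper.tri(R1)]) / max(mean(D_hat[upper.tri(D_hat)]) / 2, 1e-9), 1e-6)
  opt <- stats::optim(c(log(w0), log(q0)), f, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-10))
  list(log_w = opt$par[1], log_q = opt$par[2])
}

# Internal workhorse: penalized ML fit of (W, q), optionally with fixed
# events; free_c additionally optimizes the last event's source fraction.
fit_surface <- function(D_hat, grid, demes, p, lambda_w, lambda_q,
                        init = NULL, events = list(), maxit = 1000,
                        pgtol = 1e-7, factr = 1e4, free_c = FALSE) {
  ctx <- make_fit_context(D_hat, grid, demes, p, lambda_w, lambda_q, events)
  ctx$free_c <- free_c && length(events) > 0
  me <- ctx$n_edges
  if (is.null(init)) {
    ci <- constant_init(D_hat, grid, demes, p)
    theta0 <- c(rep(ci$log_w, me), rep(ci$log_q, ctx$o))
  } else {
    theta0 <- c(log(init$w), log(init$q))
  }
  if (ctx$free_c) theta0 <- c(theta0, events[[length(events)]]$c)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta) {
    key <- cache$theta
    if (!is.null(key) && length(key) == length(theta) && all(key == theta))
      return(cache$res)
    res <- surface_objective(theta, ctx)
    cache$theta <- theta
    cache$res <- res
    res
  }
  fn <- function(theta) {
    r <- tryCatch(evaluate(theta), error = function(e) NULL)
    if (is.null(r)) return(1e12)
    r$value
  }
  gr <- function(theta) {
    r <- tryCatch(evaluate(theta), error = function(e) NULL)
    if (is.null(r)) return(numeric(length(theta)))
    r$grad
  }
  lower <- rep(log(1e-10), length(theta0))
  upper <- rep(log(1e10), length(theta0))
  if (ctx$free_c) { lower[length(lower)] <- 0; upper[length(upper)] <- 1 }
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = maxit, pgtol = pgtol,
                                     factr = factr))
  w <- exp(opt$par[seq_len(me)])
  q <- exp(opt$par[me + seq_len(ctx$o)])
  if (ctx$free_c)
    events[[length(events)]]$c <- opt$par[length(opt$par)]
  surface <- new_migration_surface(grid, demes, w, q, lambda_w, lambda_q)
  final <- surface_objective(opt$par, ctx)
  Delta <- fitted_distances(surface, events)
  diagnostics <- list(
    nll = final$value, unpenalized_nll = final$nll,
    r_squared = model_r_squared(D_hat, Delta),
    converged = opt$convergence == 0, n_iter = opt$counts[["function"]],
    message = opt$message)
  list(surface = surface, diagnostics = diagnostics, Delta = Delta,
       events = events)
}

# Expected distances over observed demes under a surface plus fixed events.
fitted_distances <- function(surface, events = list()) {
  demes <- surface$demes
  if (!length(events)) return(expected_distances(surface))
  sources <- unlist(lapply(events, `[[`, "source"))
  V <- sort(unique(c(demes, sources)))
  Lp <- surface_pinv(surface)
  dLp <- diag(Lp)
  R_V <- outer(dLp[V], dLp[V], "+") - 2 * Lp[V, V, drop = FALSE]
  diag(R_V) <- 0
  q_V <- numeric(length(V))
  q_V[match(demes, V)] <- surface$q
  for (ev in events) {
    if (!is.null(ev$gamma)) q_V[match(ev$source, V)] <- sum(ev$gamma * surface$q)
  }
  T <- coal_times_from_Rq(R_V, pmax(q_V, 1e-8))
  for (ev in events)
    T <- post_event_coal_times(T, match(ev$source, V), match(ev$dest, V), ev$c)
  delta_from_coal_times(T)[match(demes, V), match(demes, V), drop = FALSE]
}

#' Fit the baseline effective migration surface
#'
#' Penalized Wishart maximum likelihood over per-edge log-weights and
#' per-observed-deme log-variances. The penalty is
#' `lambda_w * sum((log w_e - log w_f)^2)` over pairs of edges sharing a node
#' (smoothness) plus `lambda_q * sum((log q_i - mean(log q))^2)` (similarity
#' of deme variances). Optimization is quasi-Newton (L-BFGS-B) on
#' log-parameters with analytic gradients, initialized at a constant-weight,
#' constant-variance fit.
#'
#' @param D_hat o x o observed genetic distance matrix (or a
#'   `distance_bundle`, in which case `p` is taken from it).
#' @param grid a `spatial_grid`.
#' @param assignment a `sample_assignment` (defines the observed demes).
#' @param lambda_w,lambda_q penalty scalars (>= 0).
#' @param p SNP count; required when `D_hat` is a plain matrix.
#' @param init optional list(w, q) of starting values.
#' @param maxit,pgtol optimizer controls.
#' @return list with `surface` (a `migration_surface`), `diagnostics`
#'   (r_squared, nll, converged, n_iter) and `Delta` (fitted distances).
#' @export
fit_baseline <- function(D_hat, grid, assignment, lambda_w = 1, lambda_q = 1,
                         p = NULL, init = NULL, maxit = 1000, pgtol = 1e-7) {
  if (inherits(D_hat, "distance_bundle")) {
    p <- D_hat$p
    D <- D_hat$D_hat
  } else D <- D_hat
  if (is.null(p)) stop("p (SNP count) required")
  if (lambda_w < 0 || lambda_q < 0) stop("penalties must be non-negative")
  fit_surface(D, grid, assignment$observed_demes, p, lambda_w, lambda_q,
              init = init, maxit = maxit, pgtol = pgtol)
}

#' Model fit R-squared
#'
#' Squared Pearson correlation between the upper triangles of the observed and
#' fitted distance matrices.
#'
#' @param D_hat,Delta_fitted matched o x o matrices.
#' @return scalar in \[0, 1\].
#' @export
model_r_squared <- function(D_hat, Delta_fitted) {
  x <- D_hat[upper.tri(D_hat)]
  y <- Delta_fitted[upper.tri(Delta_fitted)]
  if (stats::sd(y) == 0) stop("fitted distances are constant: R^2 undefined")
  stats::cor(x, y)^2
}

#' Leave-one-deme-out cross-validation for the penalty parameters
#'
#' For each (lambda, lambda_q) pair, each observed deme is held out in turn:
#' the surface is fitted to the remaining demes, the held-out deme's variance
#' is kriged from the fitted variances (see [krige_variance()]), and the
#' squared error between the held-out row of D_hat and its prediction is
#' accumulated.
#'
#' @param D_hat observed distances (matrix or `distance_bundle`).
#' @param grid,assignment as in [fit_baseline()].
#' @param lambda_grid,lambda_q_grid candidate penalty values.
#' @param p SNP count when `D_hat` is a matrix.
#' @param maxit optimizer iterations per fold fit.
#' @return list with `lambda_cv`, `lambda_q_cv` and the error table `cv_table`.
#' @export
cross_validate <- function(D_hat, grid, assignment,
                           lambda_grid = 10^seq(-2, 2, length.out = 8),
                           lambda_q_grid = 10^seq(-2, 2, length.out = 8),
                           p = NULL, maxit = 300) {
  if (inherits(D_hat, "distance_bundle")) {
    p <- D_hat$p
    D <- D_hat$D_hat
  } else D <- D_hat
  if (is.null(p)) stop("p (SNP count) required")
  demes <- assignment$observed_demes
  o <- length(demes)
  if (o < 2) stop("cross-validation needs at least two observed demes")
  combos <- expand.grid(lambda = lambda_grid, lambda_q = lambda_q_grid)
  errs <- numeric(nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    err <- 0
    for (h in seq_len(o)) {
      keep <- setdiff(seq_len(o), h)
      if (length(keep) < 3) stop("too few demes to hold one out")
      fitc <- tryCatch(
        fit_surface(D[keep, keep, drop = FALSE], grid, demes[keep], p,
                    combos$lambda[ci], combos$lambda_q[ci], maxit = maxit),
        error = function(e) NULL)
      if (is.null(fitc)) { err <- Inf; break }
      sfc <- fitc$surface
      Lp <- surface_pinv(sfc)
      dLp <- diag(Lp)
      nodes <- c(demes[h], demes[keep])
      Rful <- outer(dLp[nodes], dLp[nodes], "+") - 2 * Lp[nodes, nodes]
      vg <- fit_variogram(sfc$q, Rful[-1, -1, drop = FALSE])
      qh <- krige_variance(vg, Rful[1, -1], sfc$q)
      pred <- Rful[1, -1] + qh + sfc$q
      err <- err + sum((D[h, keep] - pred)^2)
    }
    errs[ci] <- err
  }
  best <- which.min(errs)
  list(lambda_cv = combos$lambda[best], lambda_q_cv = combos$lambda_q[best],
       cv_table = cbind(combos, error = errs))
}

#' Export a fitted surface as plain-text tables
#'
#' @param fit result of [fit_baseline()].
#' @param edge_file,deme_file,json_file output paths (TSV, TSV, JSON); any may
#'   be NULL to skip.
#' @export
write_surface <- function(fit, edge_file = NULL, deme_file = NULL,
                          json_file = NULL) {
  s <- fit$surface
  if (!is.null(edge_file))
    utils::write.table(data.frame(id1 = s$grid$edges[, 1],
                                  id2 = s$grid$edges[, 2], weight = s$w),
                       edge_file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(deme_file))
    utils::write.table(data.frame(deme = s$demes, q = s$q),
                       deme_file, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(json_file))
    jsonlite::write_json(list(lambda = s$lambda_w, lambda_q = s$lambda_q,
                              r_squared = fit$diagnostics$r_squared,
                              nll = fit$diagnostics$nll),
                         json_file, auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
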