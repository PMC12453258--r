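# Long-range edge probability model: kriging of within-deme coalescent times
# at unsampled demes, and the Wishart likelihood with a pulse edge.

#' Fit an exponential variogram of deme variances against resistance distance
#'
#' Empirical semivariances 0.5 (q_i - q_j)^2 are binned into equal-count bins
#' of pairwise resistance distance and the model
#' `gamma(R) = b + C0 (1 - exp(-R / a))` (nugget b, sill C0, range a) is fitted
#' by bounded least squares from three fixed starts.
#'
#' @param q_observed fitted variances at observed demes.
#' @param R_observed o x o resistance distances among the observed demes.
#' @param n_bins number of equal-count bins (default 15, reduced when few
#'   pairs are available).
#' @return a `variogram_model`: list(b, C0, a, degenerate, R_obs, bins).
#' @export
fit_variogram <- function(q_observed, R_observed, n_bins = 15) {
  o <- length(q_observed)
  if (o < 4) stop("variogram fitting needs at least 4 observed demes")
  ut <- upper.tri(R_observed)
  r <- R_observed[ut]
  gam <- 0.5 * outer(q_observed, q_observed, "-")[ut]^2
  if (max(gam) < 1e-24) {
    return(structure(list(b = 0, C0 = 0, a = max(stats::median(r), 1e-6),
                          degenerate = TRUE, R_obs = R_observed,
                          bins = NULL), class = "variogram_model"))
  }
  n_bins <- max(3, min(n_bins, floor(length(r) / 2)))
  ord <- order(r)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  rb <- tapply(r[ord], bin, mean)
  gb <- tapply(gam[ord], bin, mean)
  obj <- function(par) {
    m <- par[1] + par[2] * (1 - exp(-rb / par[3]))
    sum((gb - m)^2)
  }
  amed <- max(stats::median(r), 1e-6)
  # bound the range by the span of the data and the sill by the empirical
  # semivariances: an unbounded fit can wander onto the unidentifiable
  # near-linear ridge (a, C0 -> Inf at fixed C0/a)
  a_max <- 3 * max(r)
  C0_max <- 10 * max(gb)
  starts <- list(c(0, max(gb), amed), c(min(gb), diff(range(gb)), amed / 3),
                 c(mean(gb) / 2, mean(gb), min(amed * 3, a_max)))
  best <- NULL
  for (s0 in starts) {
    op <- stats::optim(pmax(pmin(s0, c(max(gb), C0_max, a_max)),
                            c(0, 1e-12, 1e-9)),
                       obj, method = "L-BFGS-B",
                       lower = c(0, 0, 1e-9),
                       upper = c(max(gb), C0_max, a_max))
    if (is.null(best) || op$value < best$value) best <- op
  }
  structure(list(b = best$par[1], C0 = best$par[2], a = best$par[3],
                 degenerate = FALSE, R_obs = R_observed,
                 bins = cbind(R = as.numeric(rb), gamma = as.numeric(gb))),
            class = "variogram_model")
}

# Model semivariance at resistance distance r.
variogram_value <- function(vg, r) {
  vg$b + vg$C0 * (1 - exp(-r / vg$a))
}

#' Krige the variance of an unsampled deme
#'
#' Ordinary kriging with the fitted exponential variogram evaluated at
#' resistance distances; the weights gamma_1..gamma_o are constrained to sum
#' to one, so a constant variance field is reproduced exactly.
#'
#' @param variogram a `variogram_model` from [fit_variogram()] (carries the
#'   observed-deme resistance matrix).
#' @param r_target vector of resistance distances from the target node to each
#'   observed deme.
#' @param q_observed variances at the observed demes.
#' @param return_weights if TRUE, return list(q, weights).
#' @return kriged variance (floored at 1e-8), or a list when
#'   `return_weights = TRUE`.
#' @export
krige_variance <- function(variogram, r_target, q_observed,
                           return_weights = FALSE) {
  o <- length(q_observed)
  if (variogram$degenerate) {
    w <- rep(1 / o, o)
    q <- max(mean(q_observed), 1e-8)
    return(if (return_weights) list(q = q, weights = w) else q)
  }
  Gam <- variogram_value(variogram, variogram$R_obs)
  diag(Gam) <- 0
  A <- rbind(cbind(Gam, 1), c(rep(1, o), 0))
  rhs <- c(variogram_value(variogram, r_target), 1)
  sol <- tryCatch(solve(A + diag(1e-10, o + 1), rhs), error = function(e) NULL)
  if (is.null(sol)) {
    w <- rep(1 / o, o)
  } else w <- sol[seq_len(o)]
  q <- max(sum(w * q_observed), 1e-8)
  if (return_weights) list(q = q, weights = w) else q
}

# Scan context: everything reusable across candidate sources / values of c for
# a fixed surface and data. Holds the full-grid pseudo-inverse so resistance
# distances to any node are cheap.
lre_context <- function(D_hat, surface, p, prior_events = list()) {
  Lp <- surface_pinv(surface)
  demes <- surface$demes
  vg <- NULL
  list(D = D_hat, p = p, surface = surface, Lp = Lp, demes = demes,
       o = length(demes), wctx = wishart_context(D_hat, p),
       prior_events = prior_events)
}

# Variogram for the surface, fitted lazily.
context_variogram <- function(ctx) {
  if (!is.null(ctx$vg)) return(ctx$vg)
  dLp <- diag(ctx$Lp)
  Ro <- outer(dLp[ctx$demes], dLp[ctx$demes], "+") -
    2 * ctx$Lp[ctx$demes, ctx$demes]
  diag(Ro) <- 0
  fit_variogram(ctx$surface$q, Ro)
}

# Kriging weights for a node (NULL when the node is an observed deme).
source_gamma <- function(ctx, node, vg) {
  if (node %in% ctx$demes) return(NULL)
  dLp <- diag(ctx$Lp)
  r <- dLp[node] + dLp[ctx$demes] - 2 * ctx$Lp[node, ctx$demes]
  krige_variance(vg, r, ctx$surface$q, return_weights = TRUE)$weights
}

# nll of the data with prior events plus one new edge (source, dest, c).
# All surface parameters fixed; O(o^3) per call.
context_nll <- function(ctx, source, dest, c, gamma = NULL) {
  ev <- c(ctx$prior_events,
          list(list(source = source, dest = dest, c = c, gamma = gamma)))
  V <- sort(unique(c(ctx$demes, vapply(ev, `[[`, numeric(1), "source"))))
  dLp <- diag(ctx$Lp)
  R_V <- outer(dLp[V], dLp[V], "+") - 2 * ctx$Lp[V, V, drop = FALSE]
  diag(R_V) <- 0
  q_V <- numeric(length(V))
  q_V[match(ctx$demes, V)] <- ctx$surface$q
  for (e in ev) {
    if (!is.null(e$gamma))
      q_V[match(e$source, V)] <- max(sum(e$gamma * ctx$surface$q), 1e-8)
  }
  T <- coal_times_from_Rq(R_V, q_V)
  for (e in ev)
    T <- post_event_coal_times(T, match(e$source, V), match(e$dest, V), e$c)
  obs <- match(ctx$demes, V)
  Delta <- delta_from_coal_times(T)[obs, obs]
  wishart_nll_core(ctx$wctx, Delta)$nll
}

#' Negative log-likelihood of the model with a long-range edge
#'
#' Wishart likelihood evaluated at the post-event expected distances; reduces
#' exactly to the baseline likelihood at c = 0.
#'
#' @param D_hat observed distances over the surface's demes.
#' @param surface a `migration_surface`.
#' @param edge list with `source` (grid node id), `dest` (observed deme id),
#'   `c` (source fraction) and optionally `gamma` (kriging weights for an
#'   unsampled source; computed internally when missing).
#' @param p SNP count.
#' @return scalar nll.
#' @export
lre_nll <- function(D_hat, surface, edge, p) {
  ctx <- lre_context(D_hat, surface, p)
  gamma <- edge$gamma
  if (is.null(gamma) && !(edge$source %in% surface$demes))
    gamma <- source_gamma(ctx, edge$source, context_variogram(ctx))
  context_nll(ctx, edge$source, edge$dest, edge$c, gamma)
}

# Maximize the likelihood over c in [0,1] for a fixed source; derivative-free
# bounded search plus explicit endpoint checks.
optimize_c <- function(ctx, source, dest, gamma = NULL, tol = 1e-3) {
  f <- function(cc) context_nll(ctx, source, dest, cc, gamma)
  op <- stats::optimize(f, c(0, 1), tol = tol)
  cand <- rbind(c(op$minimum, op$objective), c(0, f(0)), c(1, f(1)))
  best <- which.min(cand[, 2])
  list(c = cand[best, 1], nll = cand[best, 2])
}

#' Pre-fit scan of candidate sources for a recipient deme
#'
#' For every grid node except the recipient, the source fraction of a pulse
#' from that node into the recipient is optimized while all surface
#' parameters stay at their baseline values. Unsampled candidate sources use a
#' kriged variance. The per-node maximized log-likelihood is the marginal
#' source-location surface.
#'
#' @param recipient observed deme id (destination of the putative edge).
#' @param D_hat observed distances.
#' @param surface fitted `migration_surface`.
#' @param p SNP count.
#' @param prior_events previously fitted edges to keep in the model.
#' @return data frame (node, c_hat, loglik) plus attribute `baseline_loglik`.
#' @export
prefit_scan <- function(recipient, D_hat, surface, p, prior_events = list()) {
  ctx <- lre_context(D_hat, surface, p, prior_events)
  vg <- context_variogram(ctx)
  nodes <- setdiff(seq_len(nrow(surface$grid$node_coords)), recipient)
  res <- matrix(NA_real_, length(nodes), 2)
  for (i in seq_along(nodes)) {
    s <- nodes[i]
    gamma <- source_gamma(ctx, s, vg)
    op <- optimize_c(ctx, s, recipient, gamma)
    res[i, ] <- c(op$c, -op$nll)
  }
  out <- data.frame(node = nodes, c_hat = res[, 1], loglik = res[, 2])
  attr(out, "baseline_loglik") <-
    -wishart_nll_core(ctx$wctx, fitted_distances(surface, prior_events))$nll
  out
}

#' Profile log-likelihood of the source fraction
#'
#' Log-likelihood on a regular grid of c in \[0, 1\] with all other
#' parameters fixed, and the interval of c within 2 log-likelihood units of
#' the maximum.
#'
#' @param edge a fitted edge (list with source, dest, and optionally gamma).
#' @param D_hat,surface,p as in [lre_nll()].
#' @param grid_step spacing of the c grid.
#' @param prior_events earlier edges kept in the model.
#' @return list(c, loglik, c_hat, interval).
#' @export
profile_likelihood_c <- function(edge, D_hat, surface, p, grid_step = 0.01,
                                 prior_events = list()) {
  ctx <- lre_context(D_hat, surface, p, prior_events)
  gamma <- edge$gamma
  if (is.null(gamma) && !(edge$source %in% surface$demes))
    gamma <- source_gamma(ctx, edge$source, context_variogram(ctx))
  cs <- seq(0, 1, by = grid_step)
  ll <- vapply(cs, function(cc)
    -context_nll(ctx, edge$source, edge$dest, cc, gamma), numeric(1))
  keep <- ll >= max(ll) - 2
  list(c = cs, loglik = ll, c_hat = cs[which.max(ll)],
       interval = range(cs[keep]))
}
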