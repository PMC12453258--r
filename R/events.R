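# Instantaneous gene-flow events in coalescent-time space, and the matching
# expected-distance updates. A pulse sends a fraction c of lineages in the
# destination deme d (backward in time) to the source deme s just before
# sampling; expected pairwise coalescent times update linearly, and expected
# genetic distances follow via Delta_ij = 4 T_ij - T_ii - T_jj.

# T matrix from resistance distances and within-deme times:
# T_ij = R_ij / 4 + (q_i + q_j) / 2 off-diagonal, T_ii = q_i.
coal_times_from_Rq <- function(R, q) {
  T <- R / 4 + outer(q, q, "+") / 2
  diag(T) <- q
  T
}

delta_from_coal_times <- function(T) {
  d <- diag(T)
  D <- 4 * T - outer(d, rep(1, length(d))) - outer(rep(1, length(d)), d)
  diag(D) <- 0
  D
}

#' Post-event expected pairwise coalescent times
#'
#' Applies the instantaneous-pulse update: a fraction `c` of lineages in deme
#' `d` derive from deme `s`. Rows/columns not involving `d` are unchanged.
#'
#' @param T symmetric matrix of expected pairwise coalescent times (diagonal =
#'   within-deme times).
#' @param s,d source and destination indices into `T` (s != d).
#' @param c source fraction in \[0, 1\].
#' @return updated symmetric matrix T'.
#' @export
post_event_coal_times <- function(T, s, d, c) {
  if (s == d) stop("source and destination must differ")
  if (c < 0 || c > 1) stop("source fraction c must lie in [0, 1]")
  Tp <- T
  k <- setdiff(seq_len(nrow(T)), c(s, d))
  Tp[k, d] <- c * T[s, k] + (1 - c) * T[k, d]
  Tp[d, k] <- Tp[k, d]
  Tp[s, d] <- Tp[d, s] <- c * T[s, s] + (1 - c) * T[s, d]
  Tp[d, d] <- (1 - c)^2 * T[d, d] + 2 * c * (1 - c) * T[s, d] + c^2 * T[s, s]
  Tp
}

# Adjoint of post_event_coal_times for gradient propagation. M holds
# d nll / d t'_ij for the independent parameters (upper triangle + diagonal),
# stored as a symmetric matrix; returns the same convention for T.
event_adjoint <- function(M, s, d, c) {
  n <- nrow(M)
  k <- setdiff(seq_len(n), c(s, d))
  Min <- M
  Min[d, ] <- 0; Min[, d] <- 0          # row/col d of T' overwritten by event
  a_kd <- M[k, d]
  Min[k, s] <- Min[k, s] + c * a_kd
  Min[s, k] <- Min[k, s]
  Min[k, d] <- Min[k, d] + (1 - c) * a_kd
  Min[d, k] <- Min[k, d]
  a_sd <- M[s, d]
  Min[s, s] <- Min[s, s] + c * a_sd
  Min[s, d] <- Min[s, d] + (1 - c) * a_sd
  a_dd <- M[d, d]
  Min[d, d] <- Min[d, d] + (1 - c)^2 * a_dd
  Min[s, d] <- Min[s, d] + 2 * c * (1 - c) * a_dd
  Min[s, s] <- Min[s, s] + c^2 * a_dd
  Min[d, s] <- Min[s, d]
  Min
}

#' Post-event expected genetic distances (single edge, closed form)
#'
#' Closed-form update of the expected distance matrix for one pulse from `s`
#' to `d` with source fraction `c`:
#' \deqn{\Delta'_{sd} = \tfrac12 (1-c)(2-c) R_{sd} + (1+c) q_s + (1-c) q_d}
#' \deqn{\Delta'_{id} = (1-c) R_{id} + c R_{is} - \tfrac12 c (1-c) R_{sd} +
#'   q_i + c q_s + (1-c) q_d, \quad i \notin \{s, d\}}
#' with all pairs not involving `d` unchanged at \eqn{R_{ij} + q_i + q_j}.
#' Identical to composing [post_event_coal_times()] with the time-to-distance
#' map.
#'
#' @param R symmetric resistance-distance matrix over the node set considered.
#' @param q within-deme time (variance) per node of that set.
#' @param s,d source and destination indices (d must be a modelled deme).
#' @param c source fraction in \[0, 1\].
#' @return symmetric expected distance matrix with zero diagonal.
#' @export
post_event_distances <- function(R, q, s, d, c) {
  if (s == d) stop("source and destination must differ")
  if (c < 0 || c > 1) stop("source fraction c must lie in [0, 1]")
  Delta <- R + outer(q, q, "+")
  diag(Delta) <- 0
  k <- setdiff(seq_len(nrow(R)), c(s, d))
  Delta[k, d] <- (1 - c) * R[k, d] + c * R[k, s] - 0.5 * c * (1 - c) * R[s, d] +
    q[k] + c * q[s] + (1 - c) * q[d]
  Delta[d, k] <- Delta[k, d]
  Delta[s, d] <- Delta[d, s] <- 0.5 * (1 - c) * (2 - c) * R[s, d] +
    (1 + c) * q[s] + (1 - c) * q[d]
  Delta
}
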