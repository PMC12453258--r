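# Wishart likelihood on projected genetic distance matrices, and its gradient
# with respect to the expected distances. The observed o x o distance matrix
# D_hat is modelled through a full-rank contrast C ((o-1) x o, rows summing to
# zero) as p * (-C D_hat C') ~ Wishart_{o-1}(-C Delta C', p) with p the number
# of unlinked SNPs. A correction term (o/2) log|CC'| makes the value invariant
# to the choice of contrast.

#' Default contrast matrix
#'
#' Rows e_i - e_o for i = 1..o-1: full rank, rows sum to zero.
#' @param o number of observed demes.
#' @return (o-1) x o matrix.
#' @export
contrast_matrix <- function(o) {
  cbind(diag(o - 1), rep(-1, o - 1))
}

# log multivariate gamma function
lmvgamma <- function(a, m) {
  m * (m - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(m)) / 2))
}

# Precompute data-side quantities reused across likelihood evaluations.
wishart_context <- function(D_hat, p, contrast = NULL) {
  o <- nrow(D_hat)
  if (o < 3) stop("need at least 3 observed demes")
  if (p < o - 1) stop("SNP count p must be at least o - 1")
  C <- if (is.null(contrast)) contrast_matrix(o) else contrast
  if (nrow(C) != o - 1 || ncol(C) != o) stop("contrast must be (o-1) x o")
  if (max(abs(rowSums(C))) > 1e-8) stop("contrast rows must sum to zero")
  m <- o - 1
  X <- -p * (C %*% D_hat %*% t(C))
  X <- (X + t(X)) / 2
  cx <- tryCatch(chol(X), error = function(e)
    stop("projected observed distance matrix is not positive definite"))
  logdetX <- 2 * sum(log(diag(cx)))
  logdetCC <- determinant(tcrossprod(C), logarithm = TRUE)$modulus[1]
  const <- -((p - m - 1) / 2) * logdetX + (p * m / 2) * log(2) +
    lmvgamma(p / 2, m) - ((m + 1) / 2) * logdetCC
  list(C = C, X = X, p = p, o = o, m = m, const = const)
}

# Negative log-likelihood (and optionally gradient wrt Delta) given a context.
# Returns list(nll, G_pair) where G_pair[i, j] (i < j) is d nll / d Delta_ij
# treating Delta as symmetric with independent upper triangle.
wishart_nll_core <- function(ctx, Delta, grad = FALSE) {
  S <- -(ctx$C %*% Delta %*% t(ctx$C))
  S <- (S + t(S)) / 2
  cs <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(cs)) stop("projected expected distance matrix is not positive definite: invalid surface")
  logdetS <- 2 * sum(log(diag(cs)))
  Sinv <- chol2inv(cs)
  nll <- (ctx$p / 2) * logdetS + sum(Sinv * ctx$X) / 2 + ctx$const
  if (!grad) return(list(nll = nll))
  M <- (ctx$p / 2) * Sinv - (Sinv %*% ctx$X %*% Sinv) / 2
  Gfull <- -crossprod(ctx$C, M %*% ctx$C)   # full-matrix convention, symmetric
  G_pair <- 2 * Gfull
  diag(G_pair) <- 0                         # diagonal of Delta is fixed at 0
  list(nll = nll, G_pair = G_pair)
}

#' Negative log Wishart likelihood of observed genetic distances
#'
#' Evaluates the negative log-density of the projected observed distance
#' matrix under the expected distances `Delta` with `p` degrees of freedom.
#' The value is invariant (to numerical precision) to the choice of full-rank
#' zero-row-sum contrast.
#'
#' @param D_hat o x o observed distance matrix.
#' @param Delta o x o expected distance matrix.
#' @param p number of unlinked SNPs (degrees of freedom).
#' @param contrast optional (o-1) x o contrast matrix; default rows e_i - e_o.
#' @return scalar negative log-likelihood.
#' @export
wishart_nll <- function(D_hat, Delta, p, contrast = NULL) {
  ctx <- wishart_context(D_hat, p, contrast)
  wishart_nll_core(ctx, Delta)$nll
}
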