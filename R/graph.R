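#' Construct a joint graph state over p genes in S subgroups
#'
#' The joint graph has gene-gene edges within each subgroup and same-gene
#' edges between pairs of subgroups; different genes in different
#' subgroups are unconnected by construction.
#'
#' @param S number of subgroups.
#' @param p number of genes.
#' @param within optional list of S symmetric binary p x p matrices with
#'   zero diagonal (defaults to empty graphs).
#' @param between optional named list (`"r_s"` for r < s) of length-p
#'   binary vectors (defaults to all zero).
#' @return An object of class `"graph_state"`.
#' @export
graph_state <- function(S, p, within = NULL, between = NULL) {
  if (is.null(within))
    within <- replicate(S, matrix(0, p, p), simplify = FALSE)
  for (G in within) {
    stopifnot(all(dim(G) == c(p, p)))
    if (any(G != t(G)) || any(diag(G) != 0))
      stop("within-subgroup adjacency must be symmetric with zero diagonal")
  }
  pairs <- if (S > 1) utils::combn(S, 2, simplify = FALSE) else list()
  if (is.null(between)) {
    between <- lapply(pairs, function(pr) numeric(p))
    names(between) <- vapply(pairs, paste, character(1), collapse = "_")
  }
  structure(list(S = S, p = p, within = within, between = between),
            class = "graph_state")
}

#' Multivariate-normal expression log-likelihood under a precision matrix
#'
#' The covariates of each subgroup are modelled as i.i.d. multivariate
#' normal with mean zero and precision Omega, giving
#' (n/2) log|Omega| - tr(S Omega)/2 with S = X'X, up to an additive
#' constant (the -np/2 log(2 pi) term) that is omitted throughout.
#'
#' @param X n x p data matrix.
#' @param omega symmetric positive-definite p x p precision matrix.
#' @return log-likelihood up to the omitted constant.
#' @export
expression_log_likelihood <- function(X, omega) {
  ch <- tryCatch(chol(omega), error = function(e)
    stop("precision matrix is not positive definite"))
  n <- nrow(X)
  Sm <- crossprod(X)
  n * sum(log(diag(ch))) - 0.5 * sum(Sm * omega)
}

#' Continuous spike-and-slab log-prior on a precision matrix
#'
#' Edgewise normal densities on the off-diagonal entries (sd nu1 when the
#' edge is present, nu0 otherwise) and Exponential(lambda/2) densities on
#' the diagonal, restricted to positive-definite matrices; the graph-
#' dependent normalizing constant is omitted (it cancels in the block
#' Gibbs construction).
#'
#' @param omega symmetric p x p matrix.
#' @param G symmetric binary adjacency with zero diagonal.
#' @param hyper a [coxbvs_hyper()] list (uses `nu0`, `nu1`, `lambda`).
#' @return log prior, `-Inf` when `omega` is not positive definite.
#' @export
precision_prior_logpdf <- function(omega, G, hyper) {
  ev <- tryCatch({chol(omega); TRUE}, error = function(e) FALSE)
  if (!ev) return(-Inf)
  up <- upper.tri(omega)
  sds <- ifelse(G[up] == 1, hyper$nu1, hyper$nu0)
  sum(stats::dnorm(omega[up], 0, sds, log = TRUE)) +
    sum(stats::dexp(diag(omega), hyper$lambda / 2, log = TRUE))
}

#' Conditional inclusion probability of a within-subgroup edge
#'
#' Gibbs full conditional for an edge indicator g_{ss,ij} given the
#' corresponding precision entry and the selection indicators of its two
#' endpoints: the slab/spike density ratio at omega_ij times the prior
#' odds pi_G/(1 - pi_G), with the MRF reward exp(2 b1 gamma_i gamma_j)
#' when both endpoints are currently selected.
#'
#' @param omega_ij precision entry (vectorized).
#' @param gamma_i,gamma_j endpoint inclusion indicators (vectorized).
#' @param hyper a [coxbvs_hyper()] list.
#' @return probability (vectorized).
#' @export
edge_conditional_within <- function(omega_ij, gamma_i, gamma_j, hyper) {
  log_odds <- log(hyper$pi_G) - log(1 - hyper$pi_G) +
    stats::dnorm(omega_ij, 0, hyper$nu1, log = TRUE) -
    stats::dnorm(omega_ij, 0, hyper$nu0, log = TRUE) +
    2 * hyper$b1 * gamma_i * gamma_j
  stats::plogis(log_odds)
}

#' Conditional inclusion probability of a between-subgroup edge
#'
#' For a same-gene edge between subgroups there is no precision entry;
#' the full conditional is the prior log-odds of pi_G shifted by the MRF
#' reward 2 b2 when the gene is selected in both subgroups.
#'
#' @param gamma_ri,gamma_si inclusion indicators of gene i in the two
#'   subgroups (vectorized).
#' @param hyper a [coxbvs_hyper()] list.
#' @return probability (vectorized).
#' @export
edge_conditional_between <- function(gamma_ri, gamma_si, hyper) {
  stats::plogis(stats::qlogis(hyper$pi_G) + 2 * hyper$b2 * gamma_ri * gamma_si)
}

#' One sweep of the block Gibbs sampler for a precision matrix
#'
#' Column-block Gibbs update of Omega under the continuous spike-and-slab
#' prior. For each column j, with the matrix partitioned into
#' (Omega_11, omega_12; omega_12', omega_22), the off-diagonal block is
#' drawn from its multivariate-normal full conditional
#' N(-C s_12, C), C = ((s_jj + lambda) Omega_11^{-1} + diag(1/v_12))^{-1}
#' where v_12 holds the edge-specific prior variances nu^2_{g_ij}, and the
#' shifted diagonal entry omega_22 - omega_12' Omega_11^{-1} omega_12 is
#' drawn from Gamma(n/2 + 1, (s_jj + lambda)/2). Positive definiteness is
#' preserved exactly by this construction.
#'
#' @param X n x p data matrix (used through S = X'X).
#' @param G symmetric binary adjacency with zero diagonal.
#' @param omega current positive-definite precision matrix.
#' @param hyper a [coxbvs_hyper()] list.
#' @return updated precision matrix (symmetric, positive definite).
#' @export
block_gibbs_update_precision <- function(X, G, omega, hyper) {
  .block_gibbs_sweep(crossprod(X), nrow(X), G, omega, hyper)
}

# Same sweep from a precomputed S = X'X (avoids recomputing it each
# MCMC iteration).
.block_gibbs_sweep <- function(Sm, n, G, omega, hyper) {
  p <- ncol(omega)
  if (p == 1) {
    omega[1, 1] <- stats::rgamma(1, n / 2 + 1,
                                 rate = (Sm[1, 1] + hyper$lambda) / 2)
    return(omega)
  }
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    O11 <- omega[idx, idx, drop = FALSE]
    O11_inv <- tryCatch(chol2inv(chol(O11)), error = function(e)
      stop("Cholesky failure in block Gibbs at column ", j))
    v12 <- ifelse(G[idx, j] == 1, hyper$nu1^2, hyper$nu0^2)
    s12 <- Sm[idx, j]
    s22 <- Sm[j, j]
    Cinv <- (s22 + hyper$lambda) * O11_inv + diag(1 / v12, p - 1)
    Cchol <- chol(Cinv)
    mu <- -backsolve(Cchol, forwardsolve(t(Cchol), s12))
    w12 <- mu + backsolve(Cchol, stats::rnorm(p - 1))
    gam <- stats::rgamma(1, n / 2 + 1, rate = (s22 + hyper$lambda) / 2)
    omega[idx, j] <- w12
    omega[j, idx] <- w12
    omega[j, j] <- gam + drop(t(w12) %*% O11_inv %*% w12)
  }
  omega
}
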