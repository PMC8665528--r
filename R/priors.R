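#' Default hyperparameters for the subgroup Cox models
#'
#' Collects every fixed hyperparameter of the model in one list. The
#' defaults are the simulation-study calibration: spike sd tau = 0.0375
#' and slab inflation c = 20 (slab sd 0.75, central 95% interval
#' +/- 1.47); MRF sparsity a = -4 (prior inclusion probability
#' expit(-4) ~ 0.018) and edge reward b1 = b2 = 1; precision spike/slab
#' sds nu0 = 0.1, nu1 = 10, diagonal rate lambda = 1; prior edge
#' probability pi_G = 2/(p - 1); Bernoulli inclusion probability
#' pi_gamma = 0.02 for the subgroup/pooled baselines; gamma-process
#' weight a0 = 2.
#'
#' `preset = "protein"` switches to the calibration used for plasmode
#' protein-expression designs: nu0 = 0.6, nu1 = 360, a = -1.75,
#' b1 = b2 = 0.5, pi_gamma = 0.2.
#'
#' @param p number of genes (sets the default pi_G = 2/(p - 1)).
#' @param preset `"default"` or `"protein"`.
#' @param ... named overrides of individual entries.
#' @return list of class `"coxbvs_hyper"`.
#' @export
coxbvs_hyper <- function(p, preset = c("default", "protein"), ...) {
  preset <- match.arg(preset)
  hyper <- list(a0 = 2, tau = 0.0375, c = 20,
                a = -4, b1 = 1, b2 = 1,
                nu0 = 0.1, nu1 = 10, lambda = 1,
                # 2/(p-1) targets ~2 edges per node; clamp for tiny p
                pi_G = min(2 / (p - 1), 0.5), pi_gamma = 0.02)
  if (preset == "protein") {
    hyper$nu0 <- 0.6; hyper$nu1 <- 360
    hyper$a <- -1.75; hyper$b1 <- 0.5; hyper$b2 <- 0.5
    hyper$pi_gamma <- 0.2
  }
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(hyper))
    if (length(unknown)) stop("unknown hyperparameter(s): ",
                              paste(unknown, collapse = ", "))
    hyper[names(over)] <- over
  }
  stopifnot(hyper$tau > 0, hyper$c > 1, hyper$b1 >= 0, hyper$b2 >= 0,
            hyper$pi_gamma > 0, hyper$pi_gamma < 1,
            hyper$nu0 > 0, hyper$nu1 > hyper$nu0, hyper$lambda > 0,
            hyper$pi_G > 0, hyper$pi_G < 1, hyper$a0 > 0)
  class(hyper) <- "coxbvs_hyper"
  hyper
}

#' Spike-and-slab log-density of a regression coefficient
#'
#' The coefficient prior is a two-component normal mixture gated by the
#' inclusion indicator: N(0, tau^2) when gamma = 0 (spike) and
#' N(0, c^2 tau^2) when gamma = 1 (slab).
#'
#' @param beta coefficient value(s).
#' @param gamma inclusion indicator(s) in \{0, 1\}.
#' @param hyper a [coxbvs_hyper()] list (uses `tau`, `c`).
#' @return log prior density, vectorized over `beta`/`gamma`.
#' @export
spike_slab_logpdf <- function(beta, gamma, hyper) {
  sd <- ifelse(gamma == 1, hyper$c * hyper$tau, hyper$tau)
  stats::dnorm(beta, 0, sd, log = TRUE)
}

#' Unnormalized Markov random field log-prior on selection indicators
#'
#' Evaluates a 1'gamma + b1 gamma' G_w gamma + b2 gamma' G_b gamma, where
#' G_w collects the within-subgroup gene-gene blocks and G_b the
#' between-subgroup same-gene diagonal blocks of the joint adjacency
#' matrix. The quadratic form runs over the full symmetric adjacency, so
#' each undirected edge with both endpoints selected contributes twice.
#'
#' @param gamma S x p binary matrix of inclusion indicators.
#' @param graph a [graph_state()] object.
#' @param hyper a [coxbvs_hyper()] list (uses `a`, `b1`, `b2`).
#' @return the unnormalized log prior (normalizing constant omitted; it is
#'   constant in gamma for fixed a, b and cancels in all Gibbs ratios).
#' @export
mrf_log_prior_unnormalized <- function(gamma, graph, hyper) {
  S <- nrow(gamma)
  quad_w <- 0
  for (s in seq_len(S))
    quad_w <- quad_w + drop(gamma[s, ] %*% graph$within[[s]] %*% gamma[s, ])
  quad_b <- 0
  if (S > 1) {
    for (pair in names(graph$between)) {
      rs <- as.integer(strsplit(pair, "_")[[1]])
      quad_b <- quad_b +
        2 * sum(graph$between[[pair]] * gamma[rs[1], ] * gamma[rs[2], ])
    }
  }
  hyper$a * sum(gamma) + hyper$b1 * quad_w + hyper$b2 * quad_b
}

#' Full conditional inclusion probability of one selection indicator
#'
#' Conditional probability that gamma_{s,i} = 1 given all other
#' indicators, the graph, and (optionally) the current coefficient
#' beta_{s,i}. With the coefficient supplied this is the Gibbs update
#' used in the sampler: the MRF conditional odds
#' exp(a + 2 b1 sum_{j != i} gamma_{s,j} g_{ss,ij} +
#'        2 b2 sum_{r != s} gamma_{r,i} g_{rs,ii})
#' multiplied by the slab/spike density ratio at beta_{s,i}. With
#' `beta_si = NULL` the prior-only MRF conditional is returned.
#'
#' @param s,i subgroup and gene index.
#' @param gamma S x p binary matrix (entry (s, i) is ignored).
#' @param graph a [graph_state()] object.
#' @param hyper a [coxbvs_hyper()] list.
#' @param beta_si current coefficient, or NULL for prior-only mode.
#' @return probability in (0, 1).
#' @export
gamma_conditional_prob <- function(s, i, gamma, graph, hyper,
                                   beta_si = NULL) {
  eta <- .mrf_conditional_logit(s, i, gamma, graph, hyper)
  if (is.null(beta_si)) return(stats::plogis(eta))
  log_w1 <- stats::dnorm(beta_si, 0, hyper$c * hyper$tau, log = TRUE) + eta
  log_w0 <- stats::dnorm(beta_si, 0, hyper$tau, log = TRUE)
  stats::plogis(log_w1 - log_w0)
}

# Conditional log-odds of gamma_{s,i} = 1 under the MRF prior given all
# other indicators and the graph.
.mrf_conditional_logit <- function(s, i, gamma, graph, hyper) {
  S <- nrow(gamma)
  nb <- sum(gamma[s, -i] * graph$within[[s]][i, -i])
  cross <- 0
  if (S > 1) {
    for (r in seq_len(S)[-s]) {
      pair <- paste(sort(c(r, s)), collapse = "_")
      cross <- cross + gamma[r, i] * graph$between[[pair]][i]
    }
  }
  hyper$a + 2 * hyper$b1 * nb + 2 * hyper$b2 * cross
}

#' Independent Bernoulli log-prior on the selection indicators
#'
#' The baseline (subgroup and pooled) models replace the MRF prior by a
#' product of independent Bernoulli(pi_gamma) priors.
#'
#' @param gamma binary matrix or vector of inclusion indicators.
#' @param hyper a [coxbvs_hyper()] list (uses `pi_gamma`).
#' @return log prior.
#' @export
bernoulli_log_prior <- function(gamma, hyper) {
  k <- sum(gamma)
  k * log(hyper$pi_gamma) + (length(gamma) - k) * log(1 - hyper$pi_gamma)
}
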