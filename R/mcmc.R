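#' MCMC control settings
#'
#' @param n_iter total number of MCMC iterations (default 20000).
#' @param burn_in number of initial iterations discarded by the posterior
#'   summaries (default 10000); adaptation of the Metropolis-Hastings
#'   proposal scales stops at the end of the burn-in.
#' @param seed integer seed; a single RNG stream with a fixed draw order
#'   makes chains bit-reproducible.
#' @param adapt_window iterations between proposal-scale adaptations.
#' @param select_sweeps number of passes over the selection indicators
#'   (Gibbs plus add/delete move) per iteration; repeating the kernel
#'   leaves the posterior unchanged but speeds up exploration of the
#'   model space at short chain lengths.
#' @param store_graph store per-iteration edge indicators (`NA` = yes
#'   when p <= 50); posterior mean edge probabilities are always kept.
#' @param verbose print progress every 500 iterations.
#' @return list of class `"coxbvs_control"`.
#' @export
coxbvs_control <- function(n_iter = 20000, burn_in = 10000, seed = 1L,
                           adapt_window = 100L, select_sweeps = 3L,
                           store_graph = NA, verbose = FALSE) {
  stopifnot(n_iter > 0, burn_in >= 0, burn_in < n_iter, select_sweeps >= 1)
  list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
       seed = as.integer(seed), adapt_window = as.integer(adapt_window),
       select_sweeps = as.integer(select_sweeps),
       store_graph = store_graph, verbose = isTRUE(verbose))
}

#' Initial MCMC state: the empty model
#'
#' Starting values: empty graph, identity precision matrices, all
#' selection indicators zero, coefficients uniform on [-0.02, 0.02] and
#' baseline increments from Gamma(1, 1).
#'
#' @param S,p dimensions.
#' @param J_s integer vector of intervals per subgroup.
#' @return list with elements `gamma`, `beta`, `h`, `graph`, `omega`.
#' @export
initialize_state <- function(S, p, J_s) {
  list(gamma = matrix(0, S, p),
       beta = matrix(stats::runif(S * p, -0.02, 0.02), S, p),
       h = lapply(J_s, function(J) stats::rgamma(J, 1, 1)),
       graph = graph_state(S, p),
       omega = replicate(S, diag(p), simplify = FALSE))
}

#' Fit a Bayesian Cox model across patient subgroups
#'
#' Fits one of four Bayesian Cox proportional-hazards variable-selection
#' models by MCMC:
#' \describe{
#'   \item{`coxbvs_sl`}{the joint model: per-subgroup Cox models with
#'     spike-and-slab coefficient priors, a Markov random field prior on
#'     the selection indicators linked to a jointly inferred graph
#'     (gene-gene edges within subgroups, same-gene edges across
#'     subgroups), and Gaussian graphical structure learning on the
#'     per-subgroup precision matrices.}
#'   \item{`sub_struct`}{as above but the between-subgroup subgraph is
#'     held empty, so only within-subgroup structure informs selection.}
#'   \item{`subgroup`}{independent per-subgroup Cox models with
#'     independent Bernoulli selection priors and no graph.}
#'   \item{`pooled`}{all subgroups merged into one cohort, then fitted as
#'     the `subgroup` model.}
#' }
#' Each MCMC iteration updates, in order: the precision matrices by block
#' Gibbs, all edge indicators, all selection indicators, all regression
#' coefficients by adaptive random-walk Metropolis-Hastings, and all
#' baseline hazard increments from their approximate gamma full
#' conditionals.
#'
#' @param data a [multi_subgroup_data()] object (training data).
#' @param model model variant, see above.
#' @param hyper a [coxbvs_hyper()] list; defaults to `coxbvs_hyper(p)`.
#' @param control a [coxbvs_control()] list.
#' @param standardize standardize covariates before fitting (per subgroup,
#'   or pooled for the pooled model); the training means/sds are stored
#'   for reuse on test data. Set to `FALSE` if the data are already on
#'   the model scale.
#' @return An object of class `"coxbvs"`; see [summary.coxbvs()],
#'   [coef.coxbvs()], [predict.coxbvs()].
#' @export
coxbvs <- function(data, model = c("coxbvs_sl", "sub_struct", "subgroup",
                                   "pooled"),
                   hyper = NULL, control = coxbvs_control(),
                   standardize = TRUE) {
  model <- match.arg(model)
  cl <- match.call()
  p <- length(data$gene_names)
  if (is.null(hyper)) hyper <- coxbvs_hyper(p)
  if (model == "pooled") data <- .pool_subgroups(data)
  std_params <- NULL
  if (standardize) {
    # per-subgroup scaling; for the pooled model the merged cohort is a
    # single subgroup, so this is exactly pooled scaling
    std <- standardize(data, mode = "per_subgroup")
    data <- std$data
    std_params <- std$params
  }
  fit <- .run_chain(data, model, hyper, control)
  fit$std_params <- std_params
  fit$call <- cl
  fit
}

.pool_subgroups <- function(data) {
  sgs <- data$subgroups
  merged <- subgroup_dataset(
    do.call(rbind, lapply(sgs, `[[`, "covariates")),
    unlist(lapply(sgs, `[[`, "time"), use.names = FALSE),
    unlist(lapply(sgs, `[[`, "event"), use.names = FALSE),
    subgroup_id = "pooled")
  multi_subgroup_data(list(merged))
}

# Full Gibbs/Metropolis sampling loop shared by all model variants.
.run_chain <- function(data, model, hyper, control) {
  set.seed(control$seed)
  use_graph <- model %in% c("coxbvs_sl", "sub_struct")
  use_between <- model == "coxbvs_sl"
  S <- length(data$subgroups)
  p <- length(data$gene_names)
  n_iter <- control$n_iter
  burn_in <- control$burn_in
  store_graph <- control$store_graph
  if (is.na(store_graph)) store_graph <- p <= 50

  sub <- lapply(data$subgroups, function(sg) {
    grouped <- build_time_partition(sg)
    wb <- fit_weibull_baseline(sg, a0 = hyper$a0)
    prior_h <- baseline_increment_prior(grouped, wb)
    list(X = sg$covariates, grouped = grouped,
         cache = .likelihood_cache(grouped), weibull = wb,
         prior_shape = prior_h$shape,
         Sm = crossprod(sg$covariates), n = nrow(sg$covariates),
         J = length(grouped$risk_sets))
  })
  J_s <- vapply(sub, `[[`, integer(1), "J")

  state <- initialize_state(S, p, J_s)
  lp <- lapply(seq_len(S), function(s) drop(sub[[s]]$X %*% state$beta[s, ]))
  loglik_s <- vapply(seq_len(S), function(s)
    .grouped_loglik_lp(sub[[s]]$grouped, sub[[s]]$cache, lp[[s]],
                       state$h[[s]]), numeric(1))

  # Separate random-walk scales for the spike (gamma = 0) and slab
  # (gamma = 1) states: the two conditional posteriors of beta differ by
  # an order of magnitude in width, and a single scale adapted to the
  # spike cannot traverse the slab during short inclusion sojourns.
  prop_sd <- list(matrix(0.1, S, p), matrix(0.5, S, p))
  acc_count <- matrix(0, S, p)
  att_count <- matrix(0, S, p)
  win_acc <- list(matrix(0, S, p), matrix(0, S, p))
  win_att <- list(matrix(0, S, p), matrix(0, S, p))

  gamma_samp <- matrix(NA_real_, n_iter, S * p)
  beta_samp <- matrix(NA_real_, n_iter, S * p)
  h_samp <- lapply(J_s, function(J) matrix(NA_real_, n_iter, J))
  loglik <- numeric(n_iter)
  up <- upper.tri(matrix(0, p, p))
  n_edge_w <- sum(up)
  graph_w_samp <- if (store_graph && use_graph)
    lapply(seq_len(S), function(s) matrix(NA_integer_, n_iter, n_edge_w))
  graph_b_samp <- if (store_graph && use_between)
    lapply(state$graph$between, function(v) matrix(NA_integer_, n_iter, p))
  edge_w_sum <- replicate(S, matrix(0, p, p), simplify = FALSE)
  edge_b_sum <- lapply(state$graph$between, function(v) numeric(p))
  n_post <- 0L
  pairs <- names(state$graph$between)

  for (it in seq_len(n_iter)) {
    ## (1) precision matrices, (2) edge indicators
    if (use_graph) {
      for (s in seq_len(S)) {
        state$omega[[s]] <- .block_gibbs_sweep(sub[[s]]$Sm, sub[[s]]$n,
                                               state$graph$within[[s]],
                                               state$omega[[s]], hyper)
        pr <- edge_conditional_within(state$omega[[s]][up],
                                      (state$gamma[s, ][row(up)[up]]),
                                      (state$gamma[s, ][col(up)[up]]), hyper)
        g_new <- as.numeric(stats::runif(n_edge_w) < pr)
        Gs <- matrix(0, p, p)
        Gs[up] <- g_new
        state$graph$within[[s]] <- Gs + t(Gs)
      }
      if (use_between && S > 1) {
        for (pair in pairs) {
          rs <- as.integer(strsplit(pair, "_")[[1]])
          pr <- edge_conditional_between(state$gamma[rs[1], ],
                                         state$gamma[rs[2], ], hyper)
          state$graph$between[[pair]] <-
            as.numeric(stats::runif(p) < pr)
        }
      }
    }

    ## (3) selection indicators: Gibbs on gamma given beta, then a joint
    ## add/delete move proposing (1 - gamma, beta* ~ prior component).
    ## The move's acceptance ratio reduces to the likelihood ratio times
    ## the conditional prior odds of gamma (the proposal cancels the
    ## spike/slab densities), so the invariant distribution is unchanged;
    ## it lets beta cross between spike and slab without a random-walk
    ## excursion through the spike tail.
    for (sweep in seq_len(control$select_sweeps))
    for (s in seq_len(S)) for (i in seq_len(p)) {
      eta <- if (use_graph)
        .mrf_conditional_logit(s, i, state$gamma, state$graph, hyper)
      else stats::qlogis(hyper$pi_gamma)
      pr <- stats::plogis(
        eta + stats::dnorm(state$beta[s, i], 0, hyper$c * hyper$tau,
                           log = TRUE) -
          stats::dnorm(state$beta[s, i], 0, hyper$tau, log = TRUE))
      state$gamma[s, i] <- as.numeric(stats::runif(1) < pr)

      g_new <- 1 - state$gamma[s, i]
      sd_new <- if (g_new == 1) hyper$c * hyper$tau else hyper$tau
      beta_new <- stats::rnorm(1, 0, sd_new)
      lp_new <- lp[[s]] + (beta_new - state$beta[s, i]) * sub[[s]]$X[, i]
      ll_new <- .grouped_loglik_lp(sub[[s]]$grouped, sub[[s]]$cache,
                                   lp_new, state$h[[s]])
      log_ratio <- ll_new - loglik_s[s] + (2 * g_new - 1) * eta
      if (log(stats::runif(1)) < log_ratio) {
        state$gamma[s, i] <- g_new
        state$beta[s, i] <- beta_new
        lp[[s]] <- lp_new
        loglik_s[s] <- ll_new
      }
    }

    ## (4) regression coefficients: adaptive random-walk MH
    for (s in seq_len(S)) for (i in seq_len(p)) {
      st <- state$gamma[s, i] + 1L
      beta_cur <- state$beta[s, i]
      beta_new <- beta_cur + stats::rnorm(1, 0, prop_sd[[st]][s, i])
      lp_new <- lp[[s]] + (beta_new - beta_cur) * sub[[s]]$X[, i]
      ll_new <- .grouped_loglik_lp(sub[[s]]$grouped, sub[[s]]$cache,
                                   lp_new, state$h[[s]])
      log_ratio <- ll_new - loglik_s[s] +
        spike_slab_logpdf(beta_new, state$gamma[s, i], hyper) -
        spike_slab_logpdf(beta_cur, state$gamma[s, i], hyper)
      att_count[s, i] <- att_count[s, i] + 1
      win_att[[st]][s, i] <- win_att[[st]][s, i] + 1
      if (log(stats::runif(1)) < log_ratio) {
        state$beta[s, i] <- beta_new
        lp[[s]] <- lp_new
        loglik_s[s] <- ll_new
        acc_count[s, i] <- acc_count[s, i] + 1
        win_acc[[st]][s, i] <- win_acc[[st]][s, i] + 1
      }
    }
    if (it <= burn_in && it %% control$adapt_window == 0) {
      for (st in 1:2) {
        enough <- win_att[[st]] >= 20   # skip rarely-visited states
        rate <- win_acc[[st]] / pmax(win_att[[st]], 1)
        upd <- enough & rate > 0.44
        prop_sd[[st]][upd] <- prop_sd[[st]][upd] * 1.1
        upd <- enough & rate < 0.23
        prop_sd[[st]][upd] <- prop_sd[[st]][upd] * 0.9
        win_acc[[st]][] <- 0
        win_att[[st]][] <- 0
      }
    }

    ## (5) baseline hazard increments: the gamma distribution
    ## Gamma(a0 dH* + d_g, a0 + sum_{R-D} exp(beta'x)) approximates the
    ## full conditional (it linearizes the failure-set factors); it is
    ## used as an independence proposal with the exact Metropolis-
    ## Hastings correction, whose log-ratio reduces to the difference of
    ## sum_{l in D_g} log(1 - exp(-h u_l)) - d_g log h between proposed
    ## and current h. Intervals without events accept always.
    for (s in seq_len(S)) {
      elp <- exp(lp[[s]])
      risk_rest <- drop(sub[[s]]$cache$RmD %*% elp)
      d_g <- sub[[s]]$grouped$event_counts
      h_prop <- stats::rgamma(sub[[s]]$J,
                              shape = sub[[s]]$prior_shape + d_g,
                              rate = hyper$a0 + risk_rest)
      u_acc <- stats::runif(sub[[s]]$J)
      corr <- function(h) {
        x <- h[sub[[s]]$cache$fail_g] * elp[sub[[s]]$cache$fail_m]
        by_g <- rep(0, sub[[s]]$J)
        if (length(x)) {
          tg <- tapply(log1p(-exp(-x)), sub[[s]]$cache$fail_g, sum)
          by_g[as.integer(names(tg))] <- tg
        }
        by_g - d_g * log(h)
      }
      log_r <- corr(h_prop) - corr(state$h[[s]])
      accept <- d_g == 0 | log(u_acc) < log_r
      state$h[[s]][accept] <- h_prop[accept]
      loglik_s[s] <- .grouped_loglik_lp(sub[[s]]$grouped, sub[[s]]$cache,
                                        lp[[s]], state$h[[s]])
    }

    gamma_samp[it, ] <- as.vector(t(state$gamma))
    beta_samp[it, ] <- as.vector(t(state$beta))
    for (s in seq_len(S)) h_samp[[s]][it, ] <- state$h[[s]]
    loglik[it] <- sum(loglik_s)
    if (use_graph) {
      if (store_graph) {
        for (s in seq_len(S))
          graph_w_samp[[s]][it, ] <- state$graph$within[[s]][up]
        if (use_between)
          for (pair in pairs)
            graph_b_samp[[pair]][it, ] <- state$graph$between[[pair]]
      }
      if (it > burn_in) {
        n_post <- n_post + 1L
        for (s in seq_len(S))
          edge_w_sum[[s]] <- edge_w_sum[[s]] + state$graph$within[[s]]
        if (use_between)
          for (pair in pairs)
            edge_b_sum[[pair]] <- edge_b_sum[[pair]] +
              state$graph$between[[pair]]
      }
    }
    if (control$verbose && it %% 500 == 0)
      message("iteration ", it, "/", n_iter,
              "  log-lik = ", signif(loglik[it], 6))
    if (!is.finite(loglik[it]))
      stop("numerical failure at iteration ", it,
           ": non-finite joint log-likelihood")
  }

  colnames(gamma_samp) <- colnames(beta_samp) <-
    paste(rep(names(data$subgroups), each = p),
          rep(data$gene_names, S), sep = ".")
  edge_prob <- NULL
  if (use_graph && n_post > 0) {
    edge_prob <- list(
      within = lapply(edge_w_sum, function(m) {
        m <- m / n_post; dimnames(m) <- list(data$gene_names,
                                             data$gene_names); m
      }),
      between = lapply(edge_b_sum, function(v) {
        v <- v / n_post; names(v) <- data$gene_names; v
      }))
    names(edge_prob$within) <- names(data$subgroups)
  }
  structure(list(
    model = model, hyper = hyper, control = control,
    gene_names = data$gene_names,
    subgroup_ids = names(data$subgroups),
    S = S, p = p,
    chain = list(gamma = gamma_samp, beta = beta_samp, h = h_samp,
                 loglik = loglik,
                 graph_within = if (store_graph && use_graph) graph_w_samp,
                 graph_between = if (store_graph && use_between) graph_b_samp),
    acceptance = acc_count / pmax(att_count, 1),
    proposal_sd = prop_sd,
    edge_prob = edge_prob,
    baseline = lapply(sub, function(x)
      list(boundaries = x$grouped$boundaries, weibull = x$weibull)),
    data = data),
    class = "coxbvs")
}

#' @export
print.coxbvs <- function(x, ...) {
  cat("Bayesian Cox variable-selection model (", x$model, ")\n", sep = "")
  cat("  subgroups:", paste(x$subgroup_ids, collapse = ", "),
      " genes:", x$p, "\n")
  cat("  iterations:", x$control$n_iter, "(burn-in", x$control$burn_in,
      "), seed", x$control$seed, "\n")
  cat("  mean MH acceptance rate:", signif(mean(x$acceptance), 3), "\n")
  s <- summary(x)
  cat("  mean model size:",
      paste(signif(s$mean_model_size, 3), collapse = ", "), "\n")
  invisible(x)
}
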