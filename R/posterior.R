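#' Posterior summaries of a fitted model
#'
#' Computes, over the post-burn-in MCMC samples: posterior selection
#' probabilities, marginal posterior means and standard deviations of the
#' regression coefficients, conditional means and standard deviations
#' restricted to iterations with the variable included (NA when a
#' variable is never selected), and the mean model size m* per subgroup
#' (average number of included variables per iteration).
#'
#' @param object a fitted [coxbvs()] model.
#' @param burn_in burn-in to discard (defaults to the fitted value).
#' @param ... unused.
#' @return list of class `"summary.coxbvs"` with S x p matrices
#'   `selection_prob`, `marginal_mean`, `marginal_sd`, `conditional_mean`,
#'   `conditional_sd` and vector `mean_model_size`.
#' @export
summary.coxbvs <- function(object, burn_in = object$control$burn_in, ...) {
  stopifnot(burn_in < object$control$n_iter)
  keep <- seq.int(burn_in + 1L, object$control$n_iter)
  gm <- object$chain$gamma[keep, , drop = FALSE]
  bm <- object$chain$beta[keep, , drop = FALSE]
  S <- object$S; p <- object$p
  as_mat <- function(v) matrix(v, S, p, byrow = TRUE,
                               dimnames = list(object$subgroup_ids,
                                               object$gene_names))
  cond_mean <- cond_sd <- numeric(ncol(gm))
  for (k in seq_len(ncol(gm))) {
    sel <- gm[, k] == 1
    cond_mean[k] <- if (any(sel)) mean(bm[sel, k]) else NA_real_
    cond_sd[k] <- if (sum(sel) > 1) stats::sd(bm[sel, k]) else NA_real_
  }
  sizes <- sapply(seq_len(S), function(s)
    rowSums(gm[, (s - 1) * p + seq_len(p), drop = FALSE]))
  res <- list(selection_prob = as_mat(colMeans(gm)),
              marginal_mean = as_mat(colMeans(bm)),
              marginal_sd = as_mat(apply(bm, 2, stats::sd)),
              conditional_mean = as_mat(cond_mean),
              conditional_sd = as_mat(cond_sd),
              mean_model_size = stats::setNames(colMeans(sizes),
                                                object$subgroup_ids),
              model = object$model, n_samples = length(keep))
  class(res) <- "summary.coxbvs"
  res
}

#' @export
print.summary.coxbvs <- function(x, top = 10, ...) {
  cat("Posterior summary (", x$model, ", ", x$n_samples,
      " post-burn-in samples)\n", sep = "")
  cat("Mean model size:",
      paste(names(x$mean_model_size),
            signif(x$mean_model_size, 3), sep = " = ", collapse = ", "),
      "\n")
  for (s in rownames(x$selection_prob)) {
    ord <- order(x$selection_prob[s, ], decreasing = TRUE)
    k <- min(top, length(ord))
    cat("Subgroup ", s, " (top ", k, " by selection probability):\n",
        sep = "")
    print(data.frame(gene = colnames(x$selection_prob)[ord[seq_len(k)]],
                     prob = round(x$selection_prob[s, ord[seq_len(k)]], 3),
                     cond_mean = round(x$conditional_mean[s, ord[seq_len(k)]], 3),
                     row.names = NULL))
  }
  invisible(x)
}

#' Select the top m* variables per subgroup
#'
#' The mean model size m* (average number of included variables across
#' post-burn-in iterations) is rounded half-to-even to an integer and the
#' m* variables with the highest posterior selection probability are
#' selected; ties are broken by gene order.
#'
#' @param summary a [summary.coxbvs()] object.
#' @return named list of character vectors of selected genes per subgroup.
#' @export
select_by_model_size <- function(summary) {
  out <- list()
  for (s in rownames(summary$selection_prob)) {
    m_star <- round(summary$mean_model_size[[s]])
    pr <- summary$selection_prob[s, ]
    out[[s]] <- if (m_star == 0) character(0) else
      names(sort(-pr)[seq_len(m_star)])
  }
  out
}

#' Median probability model
#'
#' Selects all variables with posterior selection probability strictly
#' larger than 0.5; their coefficients are the marginal posterior means,
#' all others are zero. An empty selection yields the null risk score.
#'
#' @param summary a [summary.coxbvs()] object.
#' @return list with `selected` (gene names per subgroup) and `coef`
#'   (S x p coefficient matrix).
#' @export
median_probability_model <- function(summary) {
  sel_mat <- summary$selection_prob > 0.5
  coefs <- ifelse(sel_mat, summary$marginal_mean, 0)
  dimnames(coefs) <- dimnames(summary$selection_prob)
  selected <- lapply(rownames(sel_mat), function(s)
    colnames(sel_mat)[sel_mat[s, ]])
  names(selected) <- rownames(sel_mat)
  list(selected = selected, coef = coefs)
}

#' Bayesian model averaging over the top visited models
#'
#' A "model" is a distinct configuration of the joint selection indicator
#' vector visited after the burn-in. Models are ranked by the maximum
#' joint log-likelihood attained over their iterations; the coefficients
#' are the posterior means of the regression coefficients over all
#' iterations belonging to the top `n_models` models.
#'
#' @param object a fitted [coxbvs()] model.
#' @param n_models number of top models to average over (default 100).
#' @param rank_by `"model"` (distinct configurations, default) or
#'   `"iteration"` (the top `n_models` individual iterations by
#'   log-likelihood).
#' @return S x p matrix of averaged coefficients.
#' @export
bma_top_models <- function(object, n_models = 100,
                           rank_by = c("model", "iteration")) {
  rank_by <- match.arg(rank_by)
  keep <- seq.int(object$control$burn_in + 1L, object$control$n_iter)
  gm <- object$chain$gamma[keep, , drop = FALSE]
  bm <- object$chain$beta[keep, , drop = FALSE]
  ll <- object$chain$loglik[keep]
  if (rank_by == "iteration") {
    pick <- order(ll, decreasing = TRUE)[seq_len(min(n_models, length(ll)))]
  } else {
    key <- apply(gm, 1, paste, collapse = "")
    best <- tapply(ll, key, max)
    if (length(best) < n_models)
      warning("only ", length(best), " distinct models visited; using all")
    top_keys <- names(sort(best, decreasing = TRUE))[
      seq_len(min(n_models, length(best)))]
    pick <- which(key %in% top_keys)
  }
  coefs <- matrix(colMeans(bm[pick, , drop = FALSE]), object$S, object$p,
                  byrow = TRUE,
                  dimnames = list(object$subgroup_ids, object$gene_names))
  coefs
}

#' Extract coefficients from a fitted model
#'
#' @param object a fitted [coxbvs()] model.
#' @param type `"mpm"` (median probability model, default), `"bma"`
#'   (Bayesian model averaging) or `"marginal"` (marginal posterior
#'   means of all coefficients).
#' @param ... passed to [bma_top_models()] for `type = "bma"`.
#' @return S x p coefficient matrix.
#' @export
coef.coxbvs <- function(object, type = c("mpm", "bma", "marginal"), ...) {
  type <- match.arg(type)
  switch(type,
         mpm = median_probability_model(summary(object))$coef,
         bma = bma_top_models(object, ...),
         marginal = summary(object)$marginal_mean)
}

#' Trace and running-mean diagnostics
#'
#' Plots, for chosen coefficients, the MCMC trace with running mean and
#' the autocorrelation function, the standard visual convergence checks.
#'
#' @param x a fitted [coxbvs()] model.
#' @param pars column names of `x$chain$beta` (default: the two
#'   coefficients with the highest selection probability).
#' @param ... unused.
#' @export
plot.coxbvs <- function(x, pars = NULL, ...) {
  if (is.null(pars)) {
    pr <- colMeans(x$chain$gamma[seq.int(x$control$burn_in + 1L,
                                         x$control$n_iter), , drop = FALSE])
    pars <- colnames(x$chain$beta)[order(pr, decreasing = TRUE)[1:2]]
  }
  old <- graphics::par(mfrow = c(length(pars), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (pn in pars) {
    tr <- x$chain$beta[, pn]
    graphics::plot(tr, type = "l", xlab = "iteration", ylab = pn,
                   main = paste("trace:", pn))
    graphics::lines(cumsum(tr) / seq_along(tr), col = 2, lwd = 2)
    stats::acf(tr[seq.int(x$control$burn_in + 1L, length(tr))],
               main = paste("ACF:", pn))
  }
  invisible(x)
}

#' Export posterior edge inclusion probabilities as a long table
#'
#' @param object a fitted [coxbvs()] model with graph inference.
#' @return data.frame with columns `subgroup_pair`, `gene_i`, `gene_j`,
#'   `probability`; within-subgroup rows use the subgroup label for both
#'   entries of the pair.
#' @export
edge_probabilities <- function(object) {
  if (is.null(object$edge_prob))
    stop("model '", object$model, "' does not infer a graph")
  rows <- list()
  for (s in names(object$edge_prob$within)) {
    m <- object$edge_prob$within[[s]]
    up <- which(upper.tri(m), arr.ind = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup_pair = paste(s, s, sep = "-"),
      gene_i = rownames(m)[up[, 1]], gene_j = colnames(m)[up[, 2]],
      probability = m[up], stringsAsFactors = FALSE)
  }
  for (pair in names(object$edge_prob$between)) {
    v <- object$edge_prob$between[[pair]]
    rs <- object$subgroup_ids[as.integer(strsplit(pair, "_")[[1]])]
    rows[[length(rows) + 1L]] <- data.frame(
      subgroup_pair = paste(rs, collapse = "-"),
      gene_i = names(v), gene_j = names(v),
      probability = unname(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
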