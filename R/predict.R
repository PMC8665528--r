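#' Predicted survival curves for new data
#'
#' Plug-in proportional-hazards prediction
#' S(t | x) = exp(-H0(t) exp(beta'x)) with the cumulative baseline hazard
#' H0 built from the posterior-mean increments of the fitted partition
#' (step sum plus linear interpolation within the current interval).
#' Test covariates are standardized with the training parameters stored
#' in the fit.
#'
#' @param object a fitted [coxbvs()] model.
#' @param newdata a [multi_subgroup_data()] object on the original scale
#'   (subgroup labels must match the fit; any subgroups for the pooled
#'   model).
#' @param times evaluation times; must not exceed the fitted partition's
#'   final boundary. Default: each subgroup's unique observed event times.
#' @param coef_type passed to [coef.coxbvs()] (`"mpm"`, `"bma"`,
#'   `"marginal"`).
#' @param ... unused.
#' @return named list per subgroup with elements `times` and `survival`
#'   (n_test x n_times matrix).
#' @export
predict.coxbvs <- function(object, newdata, times = NULL,
                           coef_type = "mpm", ...) {
  coefs <- coef(object, type = coef_type)
  if (!is.null(object$std_params))
    newdata <- apply_standardization(newdata, object$std_params)
  keep <- seq.int(object$control$burn_in + 1L, object$control$n_iter)
  out <- list()
  for (k in seq_along(newdata$subgroups)) {
    sg <- newdata$subgroups[[k]]
    lab <- sg$subgroup_id
    # pooled model: one shared baseline and coefficient vector
    fit_s <- if (object$model == "pooled") 1L else match(lab, object$subgroup_ids)
    if (is.na(fit_s)) stop("subgroup '", lab, "' not in fitted model")
    h_mean <- colMeans(object$chain$h[[fit_s]][keep, , drop = FALSE])
    bnd <- object$baseline[[fit_s]]$boundaries
    tt <- if (is.null(times)) sort(unique(sg$time[sg$event == 1])) else times
    H0 <- .cum_baseline(tt, bnd, h_mean)
    lp <- drop(sg$covariates %*% coefs[fit_s, ])
    surv <- exp(-outer(exp(lp), H0))
    dimnames(surv) <- list(rownames(sg$covariates), signif(tt, 6))
    out[[lab]] <- list(times = tt, survival = surv)
  }
  out
}

# Cumulative baseline hazard at times t from increments over a partition,
# linear within intervals. Errors beyond the final boundary.
.cum_baseline <- function(t, boundaries, h) {
  if (any(t > boundaries[length(boundaries)]))
    stop("evaluation time beyond the fitted follow-up range")
  cs <- c(0, cumsum(h))
  g <- findInterval(t, boundaries, left.open = TRUE, rightmost.closed = FALSE)
  g <- pmax(g, 1L)
  frac <- (t - boundaries[g]) / (boundaries[g + 1L] - boundaries[g])
  H <- cs[g] + frac * h[g]
  H[t <= 0] <- 0
  H
}

#' Kaplan-Meier estimator of the censoring distribution
#'
#' Reverse Kaplan-Meier: censoring (event = 0) is treated as the event of
#' interest, so C(t) estimates P(censoring time > t). Used for inverse
#' probability of censoring weights.
#'
#' @param time observed times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return a right-continuous step function C(t).
#' @export
censoring_km <- function(time, event) {
  if (all(event == 1)) return(function(t) rep(1, length(t)))
  km <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  stats::stepfun(km$time, c(1, km$surv), right = FALSE)
}

#' IPCW Brier score at a single time point
#'
#' BS(t) = mean over test subjects of w_m(t) (1(t_m > t) - S(t|x_m))^2
#' with weights w_m(t) = 1(t_m <= t) delta_m / C(t_m) + 1(t_m > t) / C(t);
#' subjects censored before t get weight zero.
#'
#' @param surv_prob predicted survival probabilities S(t | x_m) at time t.
#' @param time,event observed test outcomes.
#' @param cens_fn censoring survival function from [censoring_km()].
#' @param t evaluation time.
#' @return the weighted Brier score.
#' @export
brier_score <- function(surv_prob, time, event, cens_fn, t) {
  alive <- time > t
  w <- numeric(length(time))
  if (any(!alive & event == 1)) {
    cw <- cens_fn(time[!alive & event == 1])
    if (any(cw <= 0)) stop("censoring survival zero at an observed event time")
    w[!alive & event == 1] <- 1 / cw
  }
  if (any(alive)) {
    ct <- cens_fn(t)
    if (ct <= 0) stop("censoring survival zero at evaluation time")
    w[alive] <- 1 / ct
  }
  mean(w * (as.numeric(alive) - surv_prob)^2)
}

#' Integrated Brier score
#'
#' IBS(t*) = (1/t*) integral of BS(t) over [0, t*], computed by the
#' trapezoidal rule over the evaluation grid; the curve is extended as a
#' constant from the first grid point back to zero and from the last
#' grid point up to t*, so a constant curve integrates to itself.
#'
#' @param bs Brier scores over `times`.
#' @param times increasing evaluation times.
#' @param t_star upper integration limit (default: last evaluation time).
#' @return scalar IBS.
#' @export
integrated_brier <- function(bs, times, t_star = max(times)) {
  stopifnot(t_star > 0, !is.unsorted(times))
  keep <- times <= t_star
  tt <- times[keep]; bb <- bs[keep]
  if (!length(tt)) stop("no evaluation times at or below t_star")
  if (tt[1] > 0) { tt <- c(0, tt); bb <- c(bb[1], bb) }
  if (tt[length(tt)] < t_star) {
    tt <- c(tt, t_star); bb <- c(bb, bb[length(bb)])
  }
  sum(diff(tt) * (utils::head(bb, -1) + utils::tail(bb, -1)) / 2) / t_star
}

#' Prediction-error evaluation on test data
#'
#' Computes the IPCW Brier score curve and integrated Brier score per
#' subgroup for a fitted model on held-out test data. The censoring
#' distribution is estimated on the training data of the same subgroup
#' (set `cens_on = "test"` to use the test outcomes instead), and the
#' evaluation grid is the unique test event times up to `t_star`,
#' defaulting to the 90th percentile of observed test times.
#'
#' @param object a fitted [coxbvs()] model.
#' @param test a [multi_subgroup_data()] object on the original scale.
#' @param coef_type coefficient summary used for the risk score
#'   (`"mpm"` or `"bma"`).
#' @param t_star upper time limit per subgroup (scalar or named vector);
#'   default the 90th percentile of the subgroup's observed test times.
#' @param cens_on `"train"` or `"test"`.
#' @return named list per subgroup with `times`, `bs`, `ibs`, `t_star`.
#' @export
prediction_error <- function(object, test, coef_type = "mpm",
                             t_star = NULL, cens_on = c("train", "test")) {
  cens_on <- match.arg(cens_on)
  out <- list()
  for (k in seq_along(test$subgroups)) {
    sg <- test$subgroups[[k]]
    lab <- sg$subgroup_id
    fit_s <- if (object$model == "pooled") 1L else match(lab, object$subgroup_ids)
    if (is.na(fit_s)) stop("subgroup '", lab, "' not in fitted model")
    ts <- if (is.null(t_star)) unname(stats::quantile(sg$time, 0.9)) else
      if (length(t_star) > 1) t_star[[lab]] else t_star
    # cap by the fitted follow-up range so the baseline is defined
    bnd <- object$baseline[[fit_s]]$boundaries
    ts <- min(ts, bnd[length(bnd)])
    times <- sort(unique(sg$time[sg$event == 1 & sg$time <= ts]))
    if (!length(times)) stop("no test event times at or below t_star in subgroup '",
                             lab, "'")
    cfun <- if (cens_on == "train") {
      tr <- object$data$subgroups[[fit_s]]
      censoring_km(tr$time, tr$event)
    } else censoring_km(sg$time, sg$event)
    pred <- predict(object,
                    multi_subgroup_data(list(sg)),
                    times = times, coef_type = coef_type)[[lab]]
    bs <- vapply(seq_along(times), function(j)
      brier_score(pred$survival[, j], sg$time, sg$event, cfun, times[j]),
      numeric(1))
    out[[lab]] <- list(times = times, bs = bs,
                       ibs = integrated_brier(bs, times, ts), t_star = ts)
  }
  out
}
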