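#' Block partial-correlation precision matrix and its covariance
#'
#' Builds a standardized precision matrix with unit diagonal and
#' off-diagonal entries `rho` inside each given block of genes (zero
#' elsewhere), then rescales its inverse so that every gene has variance
#' one. With `rho = 0.5` the pairwise partial correlations inside a
#' block are -rho/1 = -0.5: magnitude 0.5, sign negative. The signed
#' alternative with partial correlations exactly +0.5 inside a 3-block
#' (precision off-diagonals -0.5) is singular and is rejected with an
#' error.
#'
#' @param p number of genes.
#' @param blocks list of integer index vectors (disjoint).
#' @param rho off-diagonal value of the standardized precision within
#'   blocks (default 0.5).
#' @return list with `omega` (precision) and `sigma` (covariance,
#'   unit diagonal).
#' @export
block_precision_sigma <- function(p, blocks = list(), rho = 0.5) {
  if (length(blocks) > 1 && anyDuplicated(unlist(blocks)))
    stop("blocks must be disjoint")
  omega0 <- diag(p)
  for (b in blocks) {
    stopifnot(all(b >= 1), all(b <= p))
    omega0[b, b] <- rho
    diag(omega0)[b] <- 1
  }
  ev <- eigen(omega0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("requested precision matrix is not positive definite ",
         "(smallest eigenvalue ", signif(min(ev), 3),
         "); an equicorrelated k-block needs rho > -1/(k-1)")
  sigma0 <- chol2inv(chol(omega0))
  d <- sqrt(diag(sigma0))
  sigma <- sigma0 / tcrossprod(d)       # unit-variance rescaling
  omega <- chol2inv(chol(sigma))
  omega[abs(omega) < 1e-12] <- 0
  list(omega = omega, sigma = sigma)
}

#' Simulate multivariate-normal expression data
#'
#' @param sigma positive-definite covariance matrix.
#' @param n number of i.i.d. rows.
#' @param seed optional integer seed.
#' @return n x p matrix of draws with mean zero.
#' @export
simulate_expression <- function(sigma, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% chol(sigma)
}

#' Calibrate Weibull parameters from two survival probabilities
#'
#' Exact two-point inversion of S(t) = exp(-eta t^kappa): given
#' Kaplan-Meier survival probabilities S1 at t1 and S2 at t2, solves
#' kappa = log(log S1 / log S2) / log(t1 / t2) and
#' eta = -log(S1) / t1^kappa.
#'
#' @param t1,t2 times with t1 < t2.
#' @param S1,S2 survival probabilities with 0 < S2 < S1 < 1.
#' @return list with `eta` and `kappa`.
#' @export
calibrate_weibull_from_km <- function(t1, S1, t2, S2) {
  if (!(t1 < t2)) stop("need t1 < t2")
  if (!(S2 < S1 && S1 < 1 && S2 > 0)) stop("need 0 < S2 < S1 < 1")
  kappa <- log(log(S1) / log(S2)) / log(t1 / t2)
  eta <- -log(S1) / t1^kappa
  list(eta = eta, kappa = kappa)
}

#' Simulate Weibull survival with covariate effects and random censoring
#'
#' Event times are drawn by inverse transform,
#' T = (-log U / (eta exp(x beta)))^(1/kappa), U ~ Uniform(0, 1).
#' Censoring times come from the same Weibull distribution; by default
#' the censoring draw omits the covariate term (non-informative
#' censoring), which gives close to 50% censoring when the linear
#' predictor is near zero; with `censoring_covariates = TRUE` the
#' censoring distribution equals the event distribution subject-wise and
#' the censoring rate is exactly 1/2 in expectation.
#'
#' @param X n x p covariate matrix.
#' @param beta length-p effect vector.
#' @param eta,kappa Weibull parameters.
#' @param seed optional integer seed.
#' @param censoring_covariates include the covariate term in the
#'   censoring distribution (default FALSE).
#' @return list with `time` (observed), `event` (indicator), and the
#'   latent `event_time`, `censor_time`.
#' @export
simulate_survival <- function(X, beta, eta, kappa, seed = NULL,
                              censoring_covariates = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  lp <- drop(X %*% beta)
  Tt <- (-log(stats::runif(n)) / (eta * exp(lp)))^(1 / kappa)
  clp <- if (censoring_covariates) lp else 0
  Ct <- (-log(stats::runif(n)) / (eta * exp(clp)))^(1 / kappa)
  list(time = pmin(Tt, Ct), event = as.integer(Tt <= Ct),
       event_time = Tt, censor_time = Ct)
}

#' Default effect vectors of the two-subgroup expression simulation
#'
#' Genes 1-3 are prognostic only in subgroup 1, genes 7-9 only in
#' subgroup 2, and genes 4-6 share the same negative effect in both;
#' all remaining genes are noise.
#'
#' @param p number of genes (>= 9).
#' @return 2 x p effect matrix.
#' @export
default_effects <- function(p) {
  stopifnot(p >= 9)
  beta <- matrix(0, 2, p)
  beta[1, 1:3] <- 1; beta[1, 4:6] <- -1
  beta[2, 4:6] <- -1; beta[2, 7:9] <- 1
  beta
}

#' Simulate the two-subgroup expression-and-survival study design
#'
#' Generates train and test data for two subgroups that share the same
#' multivariate-normal expression distribution (unit variances; partial
#' correlations of magnitude 0.5 within the three 3-gene blocks of
#' prognostic genes 1-3, 4-6, 7-9) but differ in their effect vectors
#' and Weibull survival parameters. The Weibull parameters are calibrated
#' from Kaplan-Meier 3- and 5-year survival probabilities of two cancer
#' cohorts: (57%, 42%) for subgroup 1 and (75%, 62%) for subgroup 2.
#' Censoring times are drawn from the same Weibull as the event times,
#' giving roughly 50% censoring.
#'
#' @param p number of genes (>= 9, default 20).
#' @param n samples per subgroup (same for train and test).
#' @param effects 2 x p effect matrix (default [default_effects()]).
#' @param km_cal list of two lists `(t1, S1, t2, S2)` per subgroup.
#' @param rho within-block precision off-diagonal (default 0.5).
#' @param seed integer seed.
#' @return list with `train` and `test` ([multi_subgroup_data()]) and the
#'   generating `omega`, `sigma`, `effects`, `weibull`.
#' @export
simulate_subgroup_data <- function(p = 20, n = 100, effects = NULL,
                                   km_cal = list(
                                     list(t1 = 3, S1 = 0.57, t2 = 5, S2 = 0.42),
                                     list(t1 = 3, S1 = 0.75, t2 = 5, S2 = 0.62)),
                                   rho = 0.5, seed = 1L) {
  if (is.null(effects)) effects <- default_effects(p)
  stopifnot(nrow(effects) == 2, ncol(effects) == p)
  set.seed(seed)
  bl <- block_precision_sigma(p, blocks = list(1:3, 4:6, 7:9), rho = rho)
  wb <- lapply(km_cal, function(kc)
    calibrate_weibull_from_km(kc$t1, kc$S1, kc$t2, kc$S2))
  gene_names <- paste0("gene", seq_len(p))
  draw <- function() {
    sgs <- lapply(1:2, function(s) {
      X <- simulate_expression(bl$sigma, n)
      colnames(X) <- gene_names
      sv <- simulate_survival(X, effects[s, ], wb[[s]]$eta, wb[[s]]$kappa)
      subgroup_dataset(X, sv$time, sv$event, subgroup_id = as.character(s))
    })
    multi_subgroup_data(sgs)
  }
  list(train = draw(), test = draw(), omega = bl$omega, sigma = bl$sigma,
       effects = effects, weibull = wb)
}

#' Protein-panel effect vectors for the plasmode design
#'
#' Effects for a 20-column protein panel in which groups of columns are
#' different phospho-sites or isoforms of the same protein and share an
#' effect: columns 1-3 prognostic only in subgroup 1 (+2), columns 4-6
#' only in subgroup 2 (+2), columns 7-8 with opposite effects
#' (-1.5/+1.5 and +1.5/-1.5), columns 9-11 with a joint effect (-2),
#' and columns 12-20 noise.
#'
#' @param p number of columns (>= 11, default 20).
#' @return 2 x p effect matrix.
#' @export
plasmode_effects <- function(p = 20) {
  stopifnot(p >= 11)
  beta <- matrix(0, 2, p)
  beta[1, 1:3] <- 2
  beta[2, 4:6] <- 2
  beta[1, 7] <- -1.5; beta[2, 7] <- 1.5
  beta[1, 8] <- 1.5;  beta[2, 8] <- -1.5
  beta[, 9:11] <- -2
  beta
}

#' Fabricated correlated protein expression matrix
#'
#' Generates a synthetic stand-in for a real protein expression matrix
#' for self-contained testing of the plasmode design: 20 columns in
#' correlated groups emulating phospho-site groups of the same protein
#' (within-group correlation 0.7, unit variances).
#'
#' @param n number of samples (default 212).
#' @param seed integer seed.
#' @return n x 20 matrix with protein-style column names.
#' @export
synthetic_protein_matrix <- function(n = 212, seed = 1L) {
  set.seed(seed)
  groups <- list(1:3, 4:6, 7, 8, 9:11, 12:14, 15:18, 19, 20)
  p <- 20
  sigma <- diag(p)
  for (g in groups) sigma[g, g] <- 0.7 + 0.3 * diag(length(g))
  X <- simulate_expression(sigma, n)
  colnames(X) <- c("Akt", "Akt_pS473", "Akt_pT308",
                   "EGFR", "EGFR_pY1068", "EGFR_pY1173",
                   "AMPK_alpha", "Annexin.1",
                   "GSK3.alpha.beta", "GSK3.alpha.beta_pS21_S9", "GSK3_pS9",
                   "X14.3.3_beta", "X14.3.3_epsilon", "X14.3.3_zeta",
                   "X4E.BP1", "X4E.BP1_pS65", "X4E.BP1_pT37T46",
                   "X4E.BP1_pT70", "X53BP1", "A.Raf_pS299")
  X
}

#' Plasmode simulation from a supplied expression matrix
#'
#' Keeps a real (or fabricated) covariate matrix with its realistic
#' correlation structure, randomly divides its rows into two equally
#' large subgroups, and simulates the survival outcome per subgroup from
#' a Weibull model with the supplied effects. Weibull event and censoring
#' parameters may be given directly or calibrated from observed survival
#' data via [fit_weibull_baseline()] beforehand.
#'
#' @param expression_matrix numeric matrix (samples x proteins).
#' @param effects 2 x p effect matrix (default [plasmode_effects()]).
#' @param weibull list of two lists `(eta, kappa)` per subgroup; default
#'   uses the two cohort calibrations of [simulate_subgroup_data()].
#' @param standardize_first standardize columns before applying effects
#'   (default TRUE).
#' @param seed integer seed controlling the subgroup split and survival
#'   draws.
#' @return a [multi_subgroup_data()] object with subgroups of equal size
#'   (the odd row, if any, goes to subgroup 2).
#' @export
make_plasmode <- function(expression_matrix, effects = NULL,
                          weibull = NULL, standardize_first = TRUE,
                          seed = 1L) {
  X <- as.matrix(expression_matrix)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 columns")
  if (is.null(effects)) effects <- plasmode_effects(p)
  stopifnot(ncol(effects) == p)
  if (is.null(weibull))
    weibull <- list(calibrate_weibull_from_km(3, 0.57, 5, 0.42),
                    calibrate_weibull_from_km(3, 0.75, 5, 0.62))
  set.seed(seed)
  n <- nrow(X)
  idx1 <- sort(sample(n, floor(n / 2)))
  split_idx <- list(idx1, setdiff(seq_len(n), idx1))
  Xs <- if (standardize_first) scale(X) else X
  sgs <- lapply(1:2, function(s) {
    rows <- split_idx[[s]]
    sv <- simulate_survival(Xs[rows, , drop = FALSE], effects[s, ],
                            weibull[[s]]$eta, weibull[[s]]$kappa)
    subgroup_dataset(X[rows, , drop = FALSE], sv$time, sv$event,
                     subgroup_id = as.character(s))
  })
  multi_subgroup_data(sgs)
}
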