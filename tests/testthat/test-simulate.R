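test_that("block precision construction yields the stated partial correlations", {
  out <- block_precision_sigma(5, blocks = list())
  expect_equal(out$omega, diag(5))
  expect_equal(out$sigma, diag(5))

  out3 <- block_precision_sigma(9, blocks = list(1:3, 4:6, 7:9), rho = 0.5)
  expect_equal(unname(diag(out3$sigma)), rep(1, 9), tolerance = 1e-10)
  # partial correlation -omega_ij / sqrt(omega_ii omega_jj)
  pcor <- -out3$omega / sqrt(tcrossprod(diag(out3$omega)))
  expect_equal(pcor[1, 2], -0.5, tolerance = 1e-10)
  expect_equal(abs(pcor[4, 6]), 0.5, tolerance = 1e-10)
  expect_equal(pcor[1, 4], 0, tolerance = 1e-10)   # across blocks
  expect_equal(pcor[3, 9], 0, tolerance = 1e-10)
  ev <- eigen(out3$omega, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("the +0.5 equicorrelated partial-correlation request is singular", {
  # precision off-diagonals of -0.5 in a 3-block give eigenvalue 0
  expect_error(block_precision_sigma(9, list(1:3, 4:6, 7:9), rho = -0.5),
               "not positive definite")
})

test_that("expression simulation matches its covariance at large n", {
  bl <- block_precision_sigma(6, blocks = list(1:3), rho = 0.5)
  X <- simulate_expression(bl$sigma, 10000, seed = 2)
  expect_lt(max(abs(cov(X) - bl$sigma)), 0.05)
  expect_lt(max(abs(colMeans(X))), 3 / sqrt(10000))
  X2 <- simulate_expression(bl$sigma, 10000, seed = 2)
  expect_identical(X, X2)
})

test_that("two-point Weibull calibration inverts the survival function", {
  cal <- calibrate_weibull_from_km(3, 0.57, 5, 0.42)
  expect_equal(cal$kappa, 0.850, tolerance = 0.001)
  expect_equal(cal$eta, 0.221, tolerance = 0.001)
  expect_equal(exp(-cal$eta * 3^cal$kappa), 0.57, tolerance = 1e-12)
  expect_equal(exp(-cal$eta * 5^cal$kappa), 0.42, tolerance = 1e-12)

  cal2 <- calibrate_weibull_from_km(3, 0.75, 5, 0.62)
  expect_equal(cal2$kappa, 0.994, tolerance = 0.001)
  expect_equal(cal2$eta, 0.0965, tolerance = 0.001)

  # S(t) = exp(-t) calibrates to the unit exponential
  calE <- calibrate_weibull_from_km(1, exp(-1), 2, exp(-2))
  expect_equal(calE$eta, 1, tolerance = 1e-12)
  expect_equal(calE$kappa, 1, tolerance = 1e-12)

  expect_error(calibrate_weibull_from_km(3, 0.4, 5, 0.6), "S2 < S1")
})

test_that("survival simulation hits the calibrated survival curve", {
  cal <- calibrate_weibull_from_km(3, 0.57, 5, 0.42)
  X <- matrix(0, 10000, 1)
  sv <- simulate_survival(X, 0, cal$eta, cal$kappa, seed = 4)
  # empirical survival of the latent event times at 3 and 5 years
  expect_equal(mean(sv$event_time > 3), 0.57, tolerance = 0.015)
  expect_equal(mean(sv$event_time > 5), 0.42, tolerance = 0.015)
  # identical event/censoring distributions give ~50% censoring
  expect_equal(mean(sv$event == 0), 0.5, tolerance = 0.015)
  expect_equal(sv$time, pmin(sv$event_time, sv$censor_time))
})

test_that("covariate-matched censoring gives exactly half censoring odds", {
  set.seed(5)
  X <- matrix(rnorm(20000), 10000, 2)
  sv <- simulate_survival(X, c(1, -1), 0.3, 1, censoring_covariates = TRUE)
  expect_equal(mean(sv$event), 0.5, tolerance = 0.015)
})

test_that("the inverse-transform inversion is exact", {
  # with U = e^-1, eta = 1, kappa = 1, x beta = 0 the event time is 1;
  # verified through the quantile identity T = (-log U / eta)^(1/kappa)
  # by matching the simulated c.d.f. at that point
  X <- matrix(0, 20000, 1)
  sv <- simulate_survival(X, 0, 1, 1, seed = 6)
  expect_equal(mean(sv$event_time <= 1), 1 - exp(-1), tolerance = 0.01)
})

test_that("the two-subgroup design reproduces the stated effect pattern", {
  sim <- simulate_subgroup_data(p = 20, n = 40, seed = 3)
  expect_equal(sim$effects[1, ], c(1, 1, 1, -1, -1, -1, rep(0, 14)))
  expect_equal(sim$effects[2, ], c(0, 0, 0, -1, -1, -1, 1, 1, 1, rep(0, 11)))
  expect_equal(length(sim$train$subgroups), 2L)
  expect_equal(nrow(sim$train$subgroups[[1]]$covariates), 40)
  expect_equal(nrow(sim$test$subgroups[[2]]$covariates), 40)
  # the two cohort calibrations
  expect_equal(sim$weibull[[1]]$eta, 0.221, tolerance = 0.001)
  expect_equal(sim$weibull[[2]]$kappa, 0.994, tolerance = 0.001)

  # different seeds give different data; equal seeds identical data
  s1 <- simulate_subgroup_data(p = 9, n = 10, seed = 1)
  s2 <- simulate_subgroup_data(p = 9, n = 10, seed = 2)
  s1b <- simulate_subgroup_data(p = 9, n = 10, seed = 1)
  expect_false(identical(s1$train$subgroups[[1]]$covariates,
                         s2$train$subgroups[[1]]$covariates))
  expect_identical(s1$train$subgroups[[1]]$covariates,
                   s1b$train$subgroups[[1]]$covariates)
})

test_that("train and test are drawn from the same distribution", {
  sim <- simulate_subgroup_data(p = 9, n = 4000, seed = 8)
  x_tr <- sim$train$subgroups[[1]]$covariates[, 1]
  x_te <- sim$test$subgroups[[1]]$covariates[, 1]
  expect_gt(suppressWarnings(ks.test(x_tr, x_te)$p.value), 0.01)
  t_tr <- sim$train$subgroups[[2]]$time
  t_te <- sim$test$subgroups[[2]]$time
  expect_gt(suppressWarnings(ks.test(t_tr, t_te)$p.value), 0.01)
})

test_that("plasmode design splits rows equally and applies panel effects", {
  X <- synthetic_protein_matrix(n = 212, seed = 1)
  expect_equal(dim(X), c(212L, 20L))
  expect_equal(colnames(X)[1], "Akt")
  # phospho-site groups are strongly correlated
  expect_gt(cor(X[, 1], X[, 2]), 0.5)
  expect_lt(abs(cor(X[, 1], X[, 20])), 0.2)

  eff <- plasmode_effects(20)
  expect_equal(unname(eff[1, 1:12]),
               c(2, 2, 2, 0, 0, 0, -1.5, 1.5, -2, -2, -2, 0))
  expect_equal(unname(eff[2, 1:11]),
               c(0, 0, 0, 2, 2, 2, 1.5, -1.5, -2, -2, -2))

  pd <- make_plasmode(X, seed = 7)
  ns <- vapply(pd$subgroups, function(s) nrow(s$covariates), integer(1))
  expect_equal(unname(ns), c(106L, 106L))
  pd2 <- make_plasmode(X, seed = 7)
  expect_identical(pd$subgroups[[1]]$covariates,
                   pd2$subgroups[[1]]$covariates)
  expect_false(identical(
    pd$subgroups[[1]]$covariates,
    make_plasmode(X, seed = 8)$subgroups[[1]]$covariates))
  # rows keep the original (unstandardized) measurement scale
  expect_true(all(pd$subgroups[[1]]$covariates %in% X))
})

test_that("a p = 100 scenario generates quickly", {
  t0 <- Sys.time()
  sim <- simulate_subgroup_data(p = 100, n = 50, seed = 10)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(ncol(sim$train$subgroups[[1]]$covariates), 100L)
})
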