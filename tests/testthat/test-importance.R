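test_that("sampled lambda dataset is recomputable through the kernel API", {
  fits <- table1_fits()
  g <- size_grid(3, 40, 50)
  ds <- lambda_dataset(fits$survival, fits$growth, fits$recruitment, g,
                       n = 150, seed = 51)
  expect_equal(nrow(ds), 150)
  expect_false(anyNA(ds))
  for (i in c(1, 70, 150)) {
    k <- ipm_kernel(ds[i, setdiff(names(ds), "lambda")], g)
    expect_equal(k$lambda, ds$lambda[i], tolerance = 1e-12)
  }
})

test_that("widening the survival-intercept posterior inflates lambda variance", {
  g <- size_grid(3, 40, 40)
  tr <- as.list(vital_rate_truths()[2, ])
  make_post <- function(int_sd) {
    set.seed(52)
    structure(list(draws = tibble::tibble(
      surv_intercept = tr$surv_intercept + int_sd * rnorm(400),
      surv_slope = tr$surv_slope + 0.002 * rnorm(400),
      growth_intercept = tr$growth_intercept + 0.01 * rnorm(400),
      growth_slope = tr$growth_slope + 0.001 * rnorm(400),
      growth_sd = tr$growth_sd * exp(0.01 * rnorm(400))
    )), class = "fir_posterior")
  }
  vars <- vapply(c(0.1, 0.2, 0.4), function(sdv) {
    p <- make_post(sdv)
    var(lambda_dataset(p, p, 0.034, g, n = 400, seed = 53)$lambda)
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("surrogate learns strong signals and refuses weak ones deterministically", {
  set.seed(54)
  X <- matrix(rnorm(3000), 500, 6)
  colnames(X) <- c("a", "b", "c", "d", "e", "f")
  d <- tibble::as_tibble(X)
  d$lambda <- 0.05 * X[, 1] + rnorm(500, 0, 0.005)
  sur <- fit_surrogate(d, seed = 55)
  expect_gt(sur$r2, 0.9)
  sur2 <- fit_surrogate(d, seed = 55)
  expect_identical(predict(sur, X), predict(sur2, X))
  # pure noise response: unfaithful surrogate is refused
  d_noise <- d
  d_noise$lambda <- rnorm(500)
  expect_error(fit_surrogate(d_noise, seed = 56), "refusing")
  d_const <- d
  d_const$lambda <- 1
  expect_error(fit_surrogate(d_const, seed = 57), "constant")
  expect_error(fit_surrogate(d[1:50, ], seed = 58), "100 rows")
})

test_that("SHAP values satisfy additivity and ignore constant inputs", {
  set.seed(59)
  X <- matrix(rnorm(3000), 500, 6)
  colnames(X) <- paste0("p", 1:6)
  X[, 4] <- 2.5  # held constant
  d <- tibble::as_tibble(X)
  d$lambda <- 1 + 0.03 * X[, 1] - 0.02 * X[, 2] + rnorm(500, 0, 0.003)
  imp <- shap_importance(fit_surrogate(d, seed = 60))
  expect_lt(imp$max_additivity_error, 1e-6)
  tab <- tidy(imp)
  expect_lt(tab$mean_abs_shap[tab$parameter == "p4"], 1e-8)
  expect_equal(tab$parameter[1:2], c("p1", "p2"))
})

test_that("kernel-entry elasticities sum to one and match finite differences", {
  g <- size_grid(3, 40, 50)
  k <- ipm_kernel(vital_rate_truths()[2, ], g)
  el <- kernel_elasticity(k)
  expect_lt(abs(sum(el$elasticity) - 1), 1e-8)
  # diagonal kernel: all elasticity on the largest diagonal entry
  D <- diag(c(0.3, 0.9, 0.5))
  elD <- kernel_elasticity(D)
  expect_equal(elD$elasticity[2, 2], 1, tolerance = 1e-10)
  expect_lt(max(abs(elD$elasticity[-5])), 1e-10)
  # finite-difference sensitivities on a small random kernel
  set.seed(61)
  M <- matrix(runif(100, 0.1, 1), 10, 10)
  elM <- kernel_elasticity(M)
  lam0 <- dominant_lambda(M)
  for (idx in list(c(1, 1), c(3, 7), c(10, 10))) {
    dM <- M
    step <- 1e-6 * M[idx[1], idx[2]]
    dM[idx[1], idx[2]] <- M[idx[1], idx[2]] + step
    fd <- (dominant_lambda(dM) - lam0) / step
    expect_lt(abs(fd - elM$sensitivity[idx[1], idx[2]]) /
                abs(elM$sensitivity[idx[1], idx[2]]), 1e-4)
  }
})

test_that("survival perturbation elasticities agree with the adjoint formula", {
  g <- size_grid(3, 40, 50)
  pars <- as.list(vital_rate_truths()[2, ])
  k <- ipm_kernel(pars, g)
  es <- survival_elasticity(k, pars)
  # adjoint route: column-aggregated P elasticities
  el <- kernel_elasticity(k)
  adjoint <- colSums((k$P / k$lambda) * el$sensitivity)
  expect_lt(max(abs(es$elasticity - adjoint)), 1e-3)
  # Richardson consistency between delta and delta/2
  keep <- abs(es$elasticity) > 1e-5
  expect_lt(max(abs(es$elasticity[keep] - es$elasticity_half_delta[keep]) /
                  abs(es$elasticity[keep])), 0.02)
})

test_that("suppressed survival leaves nothing for the perturbation to move", {
  # survival ~ 0: K is the fecundity kernel alone (full recruit window keeps
  # its dominant eigenvalue positive), so scaling survival cannot move lambda
  g <- size_grid(3, 40, 40)
  pars <- list(surv_intercept = -60, surv_slope = 0, growth_intercept = 0.3,
               growth_slope = 1.005, growth_sd = 0.55, recruitment_rate = 0.034)
  fc <- fecundity_config(recruit_window = "full")
  k <- ipm_kernel(pars, g, fc)
  expect_gt(k$lambda, 1e-6)
  es <- survival_elasticity(k, pars)
  expect_lt(max(abs(es$elasticity)), 1e-6)
})

test_that("growth-mean elasticities vanish for a nearly flat growth kernel", {
  g <- size_grid(3, 40, 40)
  pars <- list(surv_intercept = 3.64, surv_slope = 0.033, growth_intercept = 0.3,
               growth_slope = 1.005, growth_sd = 500, recruitment_rate = 0.034)
  k <- ipm_kernel(pars, g)
  eg <- growth_elasticity(k, pars)
  expect_lt(max(abs(eg$elasticity)), 1e-3)
})

test_that("fecundity-constant sensitivities vanish without recruitment and sign correctly", {
  g <- ref_grid()
  tr <- vital_rate_truths()
  barren <- dplyr::mutate(tr, recruitment_rate = 0)
  for (p in c("beta_alpha", "beta_beta", "threshold")) {
    expect_equal(fecundity_sensitivity(barren, g, param = p), 0, tolerance = 1e-12)
  }
  fc_match <- fecundity_config(recruit_window = "full", m_normalization = "none")
  expect_gt(fecundity_sensitivity(tr, g, fc_match, "beta_alpha"), 0)
  expect_lt(fecundity_sensitivity(tr, g, fc_match, "beta_beta"), 0)
  expect_lt(fecundity_sensitivity(tr, g, fc_match, "threshold"), 0)
  # the default configuration shares the threshold sign
  expect_lt(fecundity_sensitivity(tr, g, param = "threshold"), 0)
})
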