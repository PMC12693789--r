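test_that("survival fit recovers the generating logistic coefficients", {
  fit <- table1_fits()$survival
  s <- tidy(fit)
  ci_int <- s[s$parameter == "surv_intercept", ]
  ci_slope <- s[s$parameter == "surv_slope", ]
  expect_gt(3.64, ci_int$hdi_low); expect_lt(3.64, ci_int$hdi_high)
  expect_gt(0.033, ci_slope$hdi_low); expect_lt(0.033, ci_slope$hdi_high)
  expect_true(all(tidy(fit)$rhat < 1.05))
  # the fitted survival curve at 10 cm is a plain inverse logit
  p10 <- plogis(ci_int$estimate + ci_slope$estimate * 10)
  expect_lt(abs(p10 - plogis(3.64 + 0.033 * 10)), 0.02)
})

test_that("fitted survival probability matches the printed 2016-2018 curve at 10 cm", {
  expect_equal(plogis(3.345 + 0.005 * 10), 0.9676, tolerance = 1e-4)
})

test_that("survival fit agrees with an independent Gibbs implementation", {
  # same model and priors in JAGS, compared on posterior means
  census <- big_census()
  pairs <- firipm:::interval_pairs(census, 2)
  fit <- table1_fits()$survival
  model <- "model {
    for (i in 1:n) { y[i] ~ dbern(ilogit(b0 + b1 * x[i])) }
    b0 ~ dnorm(0, 0.2)
    b1 ~ dnorm(0, 0.2)
  }"
  jm <- rjags::jags.model(textConnection(model),
                          data = list(y = as.integer(pairs$survived),
                                      x = pairs$x, n = nrow(pairs)),
                          n.chains = 2, n.adapt = 300, quiet = TRUE)
  sm <- rjags::coda.samples(jm, c("b0", "b1"), n.iter = 1500, progress.bar = "none")
  jags_mean <- colMeans(as.matrix(sm))
  ours <- tidy(fit)
  our_sd <- ours$std.error
  expect_lt(abs(ours$estimate[ours$parameter == "surv_intercept"] - jags_mean["b0"]),
            0.5 * our_sd[ours$parameter == "surv_intercept"])
  expect_lt(abs(ours$estimate[ours$parameter == "surv_slope"] - jags_mean["b1"]),
            0.5 * our_sd[ours$parameter == "surv_slope"])
})

test_that("all-survivor data yields a prior-bounded, high-survival posterior", {
  tr <- dplyr::mutate(one_interval_truth(2), surv_intercept = 25, surv_slope = 0)
  cen <- simulate_census(tr, n0 = 100, seed = 3)
  # the separation can also trip the R-hat warning; only the separation
  # warning is asserted
  suppressWarnings(
    expect_warning(fit <- fit_survival(cen, 1, short_mcmc(4)), "identical")
  )
  s <- tidy(fit)
  # the separation pushes the linear predictor up, but with a size covariate
  # the mass can sit on the slope: check the predictor at a typical size
  eta10 <- fit$draws$surv_intercept + fit$draws$surv_slope * 10
  expect_gt(mean(eta10 > 0), 0.95)
  expect_gt(mean(plogis(eta10)), 0.9)
  # the intercept itself stays within a few prior SDs
  expect_lt(abs(s$estimate[s$parameter == "surv_intercept"]), 3 * sqrt(5) + 1)
})

test_that("growth fit recovers coefficients and prefers the size-dependent model", {
  fit <- table1_fits()$growth
  g <- tidy(fit)
  ci <- function(p) unlist(g[g$parameter == p, c("hdi_low", "hdi_high")])
  expect_true(ci("growth_intercept")[1] < 0.303 && 0.303 < ci("growth_intercept")[2])
  expect_true(ci("growth_slope")[1] < 1.005 && 1.005 < ci("growth_slope")[2])
  expect_true(all(fit$draws$growth_sd > 0))
  # AIC computed by the module prefers the linear model over intercept-only
  expect_lt(fit$aic, fit$aic_null)
})

test_that("noise-free growth pairs concentrate sigma near zero", {
  tr <- one_interval_truth(2)
  cen <- simulate_census(dplyr::mutate(tr, growth_sd = 1e-12, surv_intercept = 20,
                                       recruitment_rate = 0),
                         n0 = 120, seed = 5)
  fit <- suppressWarnings(fit_growth(cen, 1, short_mcmc(6)))
  g <- tidy(fit)
  expect_lt(g$estimate[g$parameter == "growth_sd"], 0.01)
  expect_equal(g$estimate[g$parameter == "growth_slope"], 1.005, tolerance = 0.01)
})

test_that("growth estimate error shrinks as the sample grows", {
  tr <- one_interval_truth(2)
  err_at <- function(n0, seed) {
    cen <- simulate_census(dplyr::mutate(tr, surv_intercept = 20, recruitment_rate = 0),
                           n0 = n0, seed = seed)
    pairs <- firipm:::interval_pairs(cen, 1)
    pars <- firipm:::map_params(pairs)
    abs(pars$growth_slope - 1.005)
  }
  errs_small <- vapply(1:10, function(s) err_at(100, s), numeric(1))
  errs_big <- vapply(1:10, function(s) err_at(1000, s + 100), numeric(1))
  expect_lt(median(errs_big), median(errs_small))
})

test_that("recruitment estimate is the exact observed ratio", {
  census <- big_census()
  rec <- estimate_recruitment(census, 2)
  expect_equal(rec$rate * rec$n_parents, rec$n_recruits)
  # hand-built table: 18 recruits over 1000 parents
  toy <- tibble::tibble(
    tree_id = c(1:1000, 1:982, 2001:2018),
    census_index = rep(c(0L, 1L), c(1000, 1000)),
    dbh_cm = 10, alive = TRUE,
    is_recruit = rep(c(FALSE, FALSE, TRUE), c(1000, 982, 18))
  )
  expect_equal(estimate_recruitment(toy, 1)$rate, 0.018)
  no_rec <- dplyr::filter(toy, !.data$is_recruit)
  expect_equal(estimate_recruitment(no_rec, 1)$rate, 0)
  expect_error(estimate_recruitment(dplyr::mutate(toy, alive = FALSE), 1), "live")
})

test_that("annual demographic rates follow the printed formulas", {
  expect_equal(annual_demographic_rates(100, 100, 0, 2)$annual_mortality_pct, 0)
  r <- annual_demographic_rates(100, 96, 4, 2)
  expect_equal(r$annual_mortality_pct, (1 - 0.96^0.5) * 100, tolerance = 1e-10)
  expect_equal(r$annual_mortality_pct, 2.0204, tolerance = 1e-4)
  # the printed recruitment annualisation is a root of the ratio
  expect_equal(r$annual_recruitment_pct, 20)
  # compound alternative stays commensurate with mortality
  rc <- annual_demographic_rates(100, 96, 4, 2, recruitment_formula = "compound")
  expect_equal(rc$annual_recruitment_pct, (1 - 0.96^0.5) * 100, tolerance = 1e-10)
  expect_error(annual_demographic_rates(100, 101, 0, 2), "exceed")
})
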