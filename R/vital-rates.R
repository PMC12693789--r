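#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Pair each tree alive at the interval's start census with its fate (and new
# size, if it survived) at the end census. `interval` is 1-based: interval k
# spans census_index k-1 -> k.
interval_pairs <- function(census, interval) {
  k <- as.integer(interval)
  start <- dplyr::filter(census, .data$census_index == k - 1L, .data$alive)
  end <- dplyr::filter(census, .data$census_index == k, !.data$is_recruit)
  if (nrow(start) == 0) rlang::abort(paste0("no live trees at census ", k - 1L))
  dplyr::inner_join(
    dplyr::select(start, "tree_id", x = "dbh_cm"),
    dplyr::select(end, "tree_id", x_new = "dbh_cm", survived = "alive"),
    by = "tree_id"
  )
}

new_fir_posterior <- function(model, chains, aic, aic_null, n, mle, prior) {
  diag <- mcmc_diagnostics(chains)
  if (any(!diag$pass, na.rm = TRUE) || anyNA(diag$rhat)) {
    rlang::warn(paste0(model, " fit: R-hat above 1.01 (or undefined) for: ",
                       paste(diag$parameter[!diag$pass | is.na(diag$rhat)], collapse = ", ")))
  }
  structure(
    list(model = model, chains = chains, draws = draws_tibble(chains),
         diagnostics = diag, aic = aic, aic_null = aic_null, n = n,
         mle = mle, prior = prior),
    class = "fir_posterior"
  )
}

#' Fit the Bayesian size-dependent survival model for one census interval
#'
#' Survival over the interval is modelled as a logistic regression on diameter
#' at the interval start: `logit p(x) = b0 + b1 * x`, with independent
#' `Normal(0, variance 5)` priors on both coefficients. Sampling is by
#' random-walk Metropolis started at the posterior mode with a
#' mode-curvature proposal; AIC is computed at the maximum-likelihood point
#' (k = 2), alongside the AIC of an intercept-only null.
#'
#' @param census A census tibble (see [simulate_census()]).
#' @param interval 1-based interval index (interval k spans census k-1 to k).
#' @param settings [mcmc_settings()].
#' @param prior_var Prior variance of the coefficients (default 5).
#' @return A `fir_posterior` object; see [tidy.fir_posterior()],
#'   [glance.fir_posterior()], [mcmc_diagnostics()].
#' @examples
#' census <- simulate_census(vital_rate_truths(), n0 = 300, seed = 1)
#' fit <- fit_survival(census, 2, mcmc_settings(chains = 2, warmup = 200, iter = 200, seed = 1))
#' tidy(fit)
#' @export
fit_survival <- function(census, interval, settings = mcmc_settings(),
                         prior_var = 5) {
  pairs <- interval_pairs(census, interval)
  if (nrow(pairs) < 20) {
    rlang::abort("interval has fewer than 20 individuals with known fate")
  }
  x <- pairs$x
  y <- as.integer(pairs$survived)
  if (length(unique(y)) == 1) {
    rlang::warn("all outcomes identical in this interval; posterior is prior-dominated")
  }
  glm_fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  aic <- as.numeric(stats::AIC(glm_fit))
  aic_null <- as.numeric(stats::AIC(suppressWarnings(
    stats::glm(y ~ 1, family = stats::binomial()))))
  log_post <- function(th) {
    eta <- th[1] + th[2] * x
    sum(ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE))) +
      sum(stats::dnorm(th, 0, sqrt(prior_var), log = TRUE))
  }
  opt <- stats::optim(c(0, 0), function(th) -log_post(th), method = "BFGS",
                      hessian = TRUE)
  vc <- curvature_vcov(opt$hessian)
  chains <- mh_sample(log_post, opt$par, vc,
                      c("surv_intercept", "surv_slope"), settings)
  new_fir_posterior("survival", chains, aic, aic_null, length(y),
                    mle = stats::coef(glm_fit), prior = list(coef_var = prior_var))
}

#' Fit the Bayesian size-dependent growth model for one census interval
#'
#' Surviving trees' next diameters are modelled as
#' `x' ~ Normal(b0 + b1 * x, sigma)` with `Normal(0, variance 5)` priors on
#' the coefficients and a `HalfNormal(scale 5)` prior on `sigma`. AIC is
#' computed at the maximum-likelihood fit (k = 3), alongside an
#' intercept-only null AIC.
#'
#' @inheritParams fit_survival
#' @param prior_sigma_scale Half-normal scale for `sigma` (default 5).
#' @return A `fir_posterior` with parameters `growth_intercept`,
#'   `growth_slope`, `growth_sd`.
#' @export
fit_growth <- function(census, interval, settings = mcmc_settings(),
                       prior_var = 5, prior_sigma_scale = 5) {
  pairs <- dplyr::filter(interval_pairs(census, interval), .data$survived)
  if (nrow(pairs) < 20) {
    rlang::abort("interval has fewer than 20 survivor size pairs")
  }
  x <- pairs$x
  y <- pairs$x_new
  lm_fit <- stats::lm(y ~ x)
  aic <- as.numeric(stats::AIC(lm_fit))
  aic_null <- as.numeric(stats::AIC(stats::lm(y ~ 1)))
  # sampled on (b0, b1, log sigma); half-normal prior on sigma with Jacobian
  log_post <- function(th) {
    sig <- exp(th[3])
    sum(stats::dnorm(y, th[1] + th[2] * x, sig, log = TRUE)) +
      sum(stats::dnorm(th[1:2], 0, sqrt(prior_var), log = TRUE)) +
      stats::dnorm(sig, 0, prior_sigma_scale, log = TRUE) + log(2) + th[3]
  }
  init <- c(stats::coef(lm_fit), log(max(stats::sigma(lm_fit), 1e-6)))
  opt <- stats::optim(init, function(th) -log_post(th), method = "BFGS",
                      hessian = TRUE)
  vc <- curvature_vcov(opt$hessian)
  chains <- mh_sample(log_post, opt$par, vc,
                      c("growth_intercept", "growth_slope", ".log_sd"), settings)
  chains <- coda::mcmc.list(lapply(chains, function(m) {
    mat <- as.matrix(m)
    mat[, 3] <- exp(mat[, 3])
    colnames(mat) <- c("growth_intercept", "growth_slope", "growth_sd")
    coda::mcmc(mat)
  }))
  new_fir_posterior("growth", chains, aic, aic_null, length(y),
                    mle = c(stats::coef(lm_fit), sigma = stats::sigma(lm_fit)),
                    prior = list(coef_var = prior_var, sigma_scale = prior_sigma_scale))
}

#' Observed per-capita recruitment rate for one census interval
#'
#' The recruitment rate is the number of new recruits first observed at the
#' interval's end census divided by the number of live individuals at the
#' interval's start census.
#'
#' @inheritParams fit_survival
#' @return A `fir_recruitment` list with `rate`, `n_recruits`, `n_parents`.
#' @export
estimate_recruitment <- function(census, interval) {
  k <- as.integer(interval)
  if (k < 1) rlang::abort("interval must have a preceding census")
  n_parents <- sum(census$census_index == k - 1L & census$alive)
  if (n_parents == 0) rlang::abort("no live individuals at interval start")
  n_recruits <- sum(census$census_index == k & census$is_recruit)
  structure(
    list(rate = n_recruits / n_parents, n_recruits = n_recruits,
         n_parents = n_parents),
    class = "fir_recruitment"
  )
}

# conjugate Beta(Nr + 1, N0 - Nr + 1) posterior draws of the recruitment rate
recruitment_draws <- function(rec, n_draws, seed = NULL) {
  run <- function() stats::rbeta(n_draws, rec$n_recruits + 1, rec$n_parents - rec$n_recruits + 1)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Annual mortality and recruitment rates from census head counts
#'
#' Applies the standard census-table annualisation formulas:
#' `M = (1 - (Nt/N0)^(1/t)) * 100` and `R = (Nr/N0)^(1/t) * 100` (percent per
#' year). The printed recruitment formula is asymmetric with mortality and can
#' yield surprisingly large values for small recruit counts; an alternative
#' compound annualisation `R = (1 - (1 - Nr/N0)^(1/t)) * 100` is available via
#' `recruitment_formula = "compound"`.
#'
#' @param N0 Live stems at the previous survey.
#' @param Nt Stems surviving to the current survey (`Nt <= N0`).
#' @param Nr Newly established stems between surveys.
#' @param t Years between surveys.
#' @param recruitment_formula `"printed"` (default) or `"compound"`.
#' @return A one-row tibble with `annual_mortality_pct`,
#'   `annual_recruitment_pct` and the inputs.
#' @examples
#' annual_demographic_rates(N0 = 100, Nt = 96, Nr = 4, t = 2)
#' @export
annual_demographic_rates <- function(N0, Nt, Nr, t,
                                     recruitment_formula = c("printed", "compound")) {
  recruitment_formula <- match.arg(recruitment_formula)
  if (N0 <= 0 || t <= 0) rlang::abort("N0 and t must be positive")
  if (Nt > N0) rlang::abort("Nt cannot exceed N0")
  M <- (1 - (Nt / N0)^(1 / t)) * 100
  R <- switch(recruitment_formula,
    printed  = (Nr / N0)^(1 / t) * 100,
    compound = (1 - (1 - Nr / N0)^(1 / t)) * 100
  )
  tibble::tibble(
    annual_mortality_pct = M, annual_recruitment_pct = R,
    N0 = N0, Nt = Nt, Nr = Nr, t = t,
    recruitment_formula = recruitment_formula
  )
}

#' @describeIn fit_survival Posterior summary (mean, SD, 95% HDI) per parameter.
#' @param x,object A `fir_posterior`.
#' @param ... Unused.
#' @method tidy fir_posterior
#' @export
tidy.fir_posterior <- function(x, ...) {
  long <- tidyr::pivot_longer(x$draws, cols = -c(".chain", ".iteration"),
                              names_to = "parameter", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$parameter),
    estimate = mean(.data$value), std.error = stats::sd(.data$value),
    hdi_low = hdi(.data$value)[1], hdi_high = hdi(.data$value)[2],
    .groups = "drop"
  )
  dplyr::left_join(out, x$diagnostics, by = "parameter")
}

#' @describeIn fit_survival One-row fit summary (AIC, null AIC, n, diagnostics).
#' @method glance fir_posterior
#' @export
glance.fir_posterior <- function(x, ...) {
  tibble::tibble(
    model = x$model, n = x$n, aic = x$aic, aic_null = x$aic_null,
    n_draws = nrow(x$draws), max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = all(x$diagnostics$pass, na.rm = TRUE)
  )
}

#' @export
print.fir_posterior <- function(x, ...) {
  cat("Bayesian", x$model, "fit:", x$n, "observations,",
      nrow(x$draws), "posterior draws\n")
  print(tidy(x))
  invisible(x)
}

#' @export
print.fir_recruitment <- function(x, ...) {
  cat(sprintf("Recruitment: %d recruits / %d parents = %.4f per individual per interval\n",
              x$n_recruits, x$n_parents, x$rate))
  invisible(x)
}
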