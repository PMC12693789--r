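#' Standardise a predictor to mean zero and unit sample SD
#'
#' @param x Numeric series with at least two distinct values.
#' @return Numeric series with mean 0 and sample SD 1.
#' @export
standardize <- function(x) {
  if (length(unique(x)) < 2) rlang::abort("cannot standardize a constant series")
  (x - mean(x)) / stats::sd(x)
}

#' Bayesian observation-error regression of log growth rate on drought
#'
#' Fits the latent-mean regression `y_t = alpha + beta * x_t` where the
#' observed log population growth rate `yhat_t` is measured with known
#' per-interval noise: `yhat_t ~ Normal(y_t, sigma_obs_t)`. The drought
#' predictor is standardised internally (mean 0, SD 1) unless already so, and
#' `alpha`, `beta` carry independent `Normal(0, variance 5)` priors. Sampling
#' is by the package's Metropolis sampler; with the observation SDs known and
#' no structural noise the posterior is exactly Gaussian, which the test suite
#' exploits as a closed-form cross-check.
#'
#' @param data A data frame with columns `y_hat` (observed log lambda),
#'   `sigma_obs` (observation SD, > 0) and `x` (drought value per interval).
#' @param settings [mcmc_settings()].
#' @param prior_var Prior variance for `alpha` and `beta` (default 5).
#' @param standardize_x Standardise `x` before fitting (default TRUE).
#' @return A `fir_regression` list with posterior `draws`, `diagnostics`, the
#'   model `data` (including the standardised predictor `x_std`), and the
#'   conjugate posterior mean/covariance (`exact_mean`, `exact_cov`).
#' @examples
#' d <- tibble::tibble(y_hat = c(0.01, 0.05, -0.02, -0.06),
#'                     sigma_obs = c(0.03, 0.04, 0.04, 0.05),
#'                     x = c(0.2, 1.1, -0.4, -0.9))
#' fit <- fit_spei_regression(d, mcmc_settings(chains = 2, warmup = 200, iter = 200, seed = 1))
#' tidy(fit)
#' @export
fit_spei_regression <- function(data, settings = mcmc_settings(),
                                prior_var = 5, standardize_x = TRUE) {
  need <- c("y_hat", "sigma_obs", "x")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("data is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(data) < 3) rlang::abort("need >= 3 intervals")
  if (any(data$sigma_obs <= 0)) rlang::abort("sigma_obs must be > 0")
  if (nrow(data) < 5) {
    rlang::warn("fewer than 5 intervals: the regression is weakly informed")
  }
  x <- if (standardize_x) standardize(data$x) else data$x
  y <- data$y_hat
  s <- data$sigma_obs
  # exact conjugate posterior (Gaussian likelihood, Gaussian prior)
  X <- cbind(1, x)
  W <- diag(1 / s^2, nrow(data))
  prec <- t(X) %*% W %*% X + diag(1 / prior_var, 2)
  exact_cov <- solve(prec)
  exact_mean <- drop(exact_cov %*% (t(X) %*% (y / s^2)))
  log_post <- function(th) {
    sum(stats::dnorm(y, th[1] + th[2] * x, s, log = TRUE)) +
      sum(stats::dnorm(th, 0, sqrt(prior_var), log = TRUE))
  }
  chains <- mh_sample(log_post, exact_mean, exact_cov, c("alpha", "beta"), settings)
  diag <- mcmc_diagnostics(chains)
  structure(
    list(draws = draws_tibble(chains), chains = chains, diagnostics = diag,
         data = dplyr::mutate(tibble::as_tibble(data), x_std = x),
         exact_mean = stats::setNames(exact_mean, c("alpha", "beta")),
         exact_cov = exact_cov, prior_var = prior_var),
    class = "fir_regression"
  )
}

#' @describeIn fit_spei_regression Table-style posterior summary: mean, 95%
#'   HDI, posterior probability of a positive effect, and the back-transform
#'   `exp(posterior mean)` (the multiplicative change in lambda per unit of
#'   the predictor), rounded to 3 decimals in `back_transform`.
#' @param x,object A `fir_regression`.
#' @param ... Unused.
#' @method tidy fir_regression
#' @export
tidy.fir_regression <- function(x, ...) {
  long <- tidyr::pivot_longer(x$draws, cols = c("alpha", "beta"),
                              names_to = "parameter", values_to = "value")
  dplyr::summarise(
    dplyr::group_by(long, .data$parameter),
    estimate = mean(.data$value), std.error = stats::sd(.data$value),
    hdi_low = hdi(.data$value)[1], hdi_high = hdi(.data$value)[2],
    p_positive = mean(.data$value > 0),
    back_transform = round(exp(mean(.data$value)), 3),
    mean_exp = mean(exp(.data$value)),
    .groups = "drop"
  )
}

#' @describeIn fit_spei_regression One-row model summary.
#' @method glance fir_regression
#' @export
glance.fir_regression <- function(x, ...) {
  s <- tidy(x)
  tibble::tibble(
    n = nrow(x$data), n_draws = nrow(x$draws),
    alpha = s$estimate[s$parameter == "alpha"],
    beta = s$estimate[s$parameter == "beta"],
    p_beta_positive = s$p_positive[s$parameter == "beta"],
    exp_beta = s$back_transform[s$parameter == "beta"],
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE)
  )
}

#' @export
print.fir_regression <- function(x, ...) {
  cat("Bayesian observation-error regression of log lambda on drought\n")
  print(tidy(x))
  invisible(x)
}
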