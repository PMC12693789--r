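#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one flat list:
#' synthetic-scenario settings, grid and fecundity configuration, MCMC
#' settings, drought settings and seeds. Every documented design-gap flag
#' (fecundity normalisation, recruit window, recruitment annualisation,
#' interval-SPEI reading) is exposed here.
#'
#' @param truths Per-interval vital-rate parameters (default
#'   [vital_rate_truths()]).
#' @param n0 Initial population size for the synthetic census.
#' @param grid_range Observed size range (cm) used to build the grid via the
#'   0.9/1.1 rule.
#' @param n_mesh Grid cells.
#' @param fc A [fecundity_config()].
#' @param mcmc [mcmc_settings()] for the vital-rate fits.
#' @param n_lambda_draws Kernel ensemble size per interval.
#' @param weather_profile Per-interval precipitation multipliers.
#' @param latitude,elevation Site coordinates for PET.
#' @param weather_months Length of the simulated weather series; it ends at
#'   the last census, with enough spin-up for the 24-month window.
#' @param spei_method Interval-SPEI reading, see [interval_spei()].
#' @param cv_folds Cross-validation folds.
#' @param seed Master seed; stage seeds are derived deterministically.
#' @return A `fir_pipeline_config` list.
#' @export
pipeline_config <- function(truths = vital_rate_truths(), n0 = 1000,
                            grid_range = c(3, 40), n_mesh = 100,
                            fc = fecundity_config(),
                            mcmc = mcmc_settings(chains = 4, warmup = 500, iter = 500),
                            n_lambda_draws = 1000,
                            weather_profile = c(0.8, 1.4, 0.8, 0.85),
                            latitude = 33.36, elevation = 1650,
                            weather_months = 168,
                            spei_method = "end",
                            cv_folds = 10,
                            seed = 1) {
  structure(
    list(truths = truths, n0 = n0, grid_range = grid_range, n_mesh = n_mesh,
         fc = fc, mcmc = mcmc, n_lambda_draws = n_lambda_draws,
         weather_profile = weather_profile, latitude = latitude,
         elevation = elevation, weather_months = weather_months,
         spei_method = spei_method, cv_folds = cv_folds, seed = seed),
    class = "fir_pipeline_config"
  )
}

#' Run the full demographic-drought pipeline on a synthetic scenario
#'
#' Executes simulate, fit (per interval), kernel ensembles, time-averaged
#' kernel, projection, SPEI, observation-error regression, SHAP importance,
#' elasticities and cross-validation, returning every stage result plus a
#' manifest of seeds. Each stage uses a seed derived from the master seed, so
#' a config reproduces its outputs exactly.
#'
#' @param config A [pipeline_config()].
#' @return A `fir_pipeline` list; see the elements `census`, `weather`,
#'   `fits`, `ensembles`, `interval_summary`, `mean_kernel`, `projection`,
#'   `spei`, `regression`, `importance`, `elasticity`, `validation`,
#'   `manifest`.
#' @export
run_ipm_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  seeds <- cfg$seed + seq_len(12) * 1009L  # distinct derived stage seeds
  n_int <- nrow(cfg$truths)
  census <- simulate_census(cfg$truths, cfg$n0, seed = seeds[1])
  # weather series ending at the final census (December), one interval = 24 months
  weather <- simulate_weather(cfg$weather_months,
                              start_year = 2024 - cfg$weather_months %/% 12,
                              profile = c(rep(1, ceiling((cfg$weather_months - 24 * n_int) / 24)),
                                          cfg$weather_profile),
                              seed = seeds[2])
  weather <- weather[seq_len(cfg$weather_months), ]
  grid <- size_grid(cfg$grid_range[1], cfg$grid_range[2], cfg$n_mesh)
  fits <- purrr::map(seq_len(n_int), function(k) {
    st <- cfg$mcmc
    st$seed <- seeds[3] + k
    list(
      survival = fit_survival(census, k, st),
      growth = fit_growth(census, k, st),
      recruitment = estimate_recruitment(census, k)
    )
  })
  n_ens <- min(cfg$n_lambda_draws, cfg$mcmc$chains * cfg$mcmc$iter)
  ensembles <- purrr::map(seq_len(n_int), function(k) {
    lambda_ensemble(fits[[k]]$survival, fits[[k]]$growth, fits[[k]]$recruitment,
                    grid, cfg$fc, n_draws = n_ens, seed = seeds[4] + k)
  })
  interval_kernels <- purrr::map(ensembles, function(e) {
    assemble_kernel(matrix(0, grid$n, grid$n), e$mean_kernel, grid, cfg$fc)
  })
  kbar <- mean_kernel(interval_kernels)
  final_sizes <- census$dbh_cm[census$census_index == n_int & census$alive]
  projection <- project_population(bin_sizes(final_sizes, grid), kbar,
                                   n_steps = 8, start_year = 2024)
  spei_series <- spei(weather, cfg$latitude, cfg$elevation)
  last <- weather[nrow(weather), ]
  ends <- tibble::tibble(
    interval = cfg$truths$interval,
    year = last$year - 2 * (n_int - seq_len(n_int)),
    month = last$month
  )
  drought <- interval_spei(spei_series, ends, method = cfg$spei_method)
  reg_data <- tibble::tibble(
    interval = cfg$truths$interval,
    y_hat = vapply(ensembles, function(e) log(e$mean), numeric(1)),
    sigma_obs = vapply(ensembles, function(e) stats::sd(log(e$lambda)), numeric(1)),
    x = drought$spei
  )
  reg_mcmc <- cfg$mcmc
  reg_mcmc$seed <- seeds[5]
  regression <- fit_spei_regression(reg_data, reg_mcmc)
  ds <- lambda_dataset(fits[[2]]$survival, fits[[2]]$growth, fits[[2]]$recruitment,
                       grid, cfg$fc, n = n_ens, seed = seeds[6])
  importance <- shap_importance(fit_surrogate(ds, seed = seeds[7]))
  kern2 <- ipm_kernel(posterior_mean_params(fits[[2]]), grid, cfg$fc,
                      R = fits[[2]]$recruitment$rate)
  elasticity <- dplyr::bind_rows(
    survival_elasticity(kern2, posterior_mean_params(fits[[2]])),
    growth_elasticity(kern2, posterior_mean_params(fits[[2]]))
  )
  validation <- cross_validate_ipm(census, k = cfg$cv_folds, grid = grid,
                                   fc = cfg$fc, seed = seeds[8])
  interval_summary <- tibble::tibble(
    interval = cfg$truths$interval,
    recruitment_rate = vapply(fits, function(f) f$recruitment$rate, numeric(1)),
    lambda_mean = vapply(ensembles, function(e) e$mean, numeric(1)),
    lambda_sd = vapply(ensembles, function(e) e$sd, numeric(1)),
    lambda_mean_kernel = vapply(ensembles, function(e) e$lambda_mean_kernel, numeric(1)),
    spei = drought$spei
  )
  structure(
    list(census = census, weather = weather, grid = grid, fits = fits,
         ensembles = ensembles, interval_summary = interval_summary,
         mean_kernel = kbar, projection = projection, spei = spei_series,
         regression = regression, importance = importance,
         elasticity = elasticity, validation = validation,
         manifest = list(config = cfg, stage_seeds = seeds,
                         package_version = as.character(utils::packageVersion("firipm")))),
    class = "fir_pipeline"
  )
}

# posterior-mean parameter set from a survival + growth + recruitment fit
posterior_mean_params <- function(fit) {
  s <- tidy(fit$survival)
  g <- tidy(fit$growth)
  est <- function(tb, p) tb$estimate[tb$parameter == p]
  list(
    surv_intercept = est(s, "surv_intercept"), surv_slope = est(s, "surv_slope"),
    growth_intercept = est(g, "growth_intercept"),
    growth_slope = est(g, "growth_slope"), growth_sd = est(g, "growth_sd"),
    recruitment_rate = fit$recruitment$rate
  )
}

#' @export
print.fir_pipeline <- function(x, ...) {
  cat("firipm pipeline run\n")
  print(x$interval_summary)
  cat(sprintf("mean-kernel lambda: %.4f\n", x$mean_kernel$lambda))
  invisible(x)
}
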