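#' Simulate a biennial individual-tree census
#'
#' Generates an individual-based census table with the generative structure the
#' vital-rate models assume: each interval, a tree of diameter `x` survives
#' with probability `plogis(surv_intercept + surv_slope * x)`; survivors draw
#' their next diameter from `Normal(growth_intercept + growth_slope * x,
#' growth_sd)`, truncated below at a small positive floor; new recruits enter
#' with a count drawn `Binomial(N0, recruitment_rate)` (or Poisson with the
#' same mean) and sizes from a Beta(1.3, 2) distribution rescaled onto
#' `recruit_window`.
#'
#' A tree found dead contributes one final row with `alive = FALSE` at the
#' census where its death is observed (its last measured diameter is carried
#' over) and no rows afterwards. A recruit's first row has `is_recruit = TRUE`.
#'
#' @param truths Data frame of per-interval vital-rate parameters, one row per
#'   interval, as returned by [vital_rate_truths()].
#' @param n0 Initial number of live trees (> 0).
#' @param recruit_window Length-2 numeric, the diameter range (cm) recruits
#'   enter in. Default `c(2.7, 5)`: below the 5 cm reproductive threshold.
#' @param init_size_sampler Function of `n` returning `n` initial diameters
#'   (cm). The default draws right-skewed diameters `3 + Gamma(1.8, scale 5)`
#'   capped at 40 cm, mimicking a small-tree-dominated subalpine stand.
#' @param recruit_dist `"binomial"` (default) or `"poisson"` recruit counts.
#' @param size_floor Lower truncation (cm) for growth draws; default 0.1.
#' @param seed Optional integer seed; the simulation is reproducible for a
#'   fixed seed and leaves the global RNG state untouched.
#'
#' @return A `fir_census` tibble with columns `tree_id`, `census_index`
#'   (0-based), `dbh_cm`, `alive`, `is_recruit`.
#' @examples
#' census <- simulate_census(vital_rate_truths(), n0 = 200, seed = 1)
#' dplyr::count(census, census_index, alive)
#' @export
simulate_census <- function(truths, n0,
                            recruit_window = c(2.7, 5),
                            init_size_sampler = NULL,
                            recruit_dist = c("binomial", "poisson"),
                            size_floor = 0.1,
                            seed = NULL) {
  validate_truths(truths)
  recruit_dist <- match.arg(recruit_dist)
  if (!is.numeric(n0) || length(n0) != 1 || n0 <= 0) {
    rlang::abort("n0 must be a single positive count")
  }
  if (recruit_window[1] >= recruit_window[2]) {
    rlang::abort("recruit_window must satisfy low < high")
  }
  if (is.null(init_size_sampler)) {
    init_size_sampler <- function(n) pmin(3 + stats::rgamma(n, shape = 1.8, scale = 5), 40)
  }
  run <- function() {
    n_int <- nrow(truths)
    size <- init_size_sampler(n0)
    id <- seq_len(n0)
    next_id <- n0 + 1L
    rows <- vector("list", n_int + 1L)
    rows[[1]] <- tibble::tibble(
      tree_id = id, census_index = 0L, dbh_cm = size,
      alive = TRUE, is_recruit = FALSE
    )
    for (k in seq_len(n_int)) {
      tr <- truths[k, ]
      n_alive <- length(id)
      p_surv <- stats::plogis(tr$surv_intercept + tr$surv_slope * size)
      survived <- stats::runif(n_alive) < p_surv
      new_size <- pmax(
        stats::rnorm(sum(survived), tr$growth_intercept + tr$growth_slope * size[survived],
                     tr$growth_sd),
        size_floor
      )
      n_rec <- switch(recruit_dist,
        binomial = stats::rbinom(1, n_alive, tr$recruitment_rate),
        poisson  = stats::rpois(1, n_alive * tr$recruitment_rate)
      )
      rec_size <- recruit_window[1] +
        diff(recruit_window) * stats::rbeta(n_rec, 1.3, 2)
      rec_id <- if (n_rec > 0) seq.int(next_id, length.out = n_rec) else integer(0)
      next_id <- next_id + n_rec
      rows[[k + 1L]] <- tibble::tibble(
        tree_id = c(id[survived], id[!survived], rec_id),
        census_index = k,
        dbh_cm = c(new_size, size[!survived], rec_size),
        alive = rep(c(TRUE, FALSE, TRUE), c(sum(survived), sum(!survived), n_rec)),
        is_recruit = rep(c(FALSE, FALSE, TRUE), c(sum(survived), sum(!survived), n_rec))
      )
      id <- c(id[survived], rec_id)
      size <- c(new_size, rec_size)
    }
    out <- dplyr::arrange(dplyr::bind_rows(rows), .data$census_index, .data$tree_id)
    new_fir_census(out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

new_fir_census <- function(x) {
  class(x) <- c("fir_census", class(x))
  x
}

#' Simulate monthly mountain weather for drought-index work
#'
#' Generates a monthly meteorological table (precipitation, mean/max/min
#' temperature, relative humidity, wind speed, solar radiation) with a
#' sinusoidal seasonal cycle plus noise, and gamma-distributed precipitation
#' whose monthly mean can be scaled per period through `profile` to create wet
#' or dry census intervals. Defaults emulate a wet subalpine site (annual mean
#' temperature ~6.4 degrees C, ~5300 mm annual precipitation).
#'
#' @param n_months Number of months (>= 48; a 24-month drought window needs at
#'   least two years of spin-up plus data to standardise against).
#' @param start_year First calendar year of the series.
#' @param baseline Named list of climate parameters; see Details. Any subset
#'   may be overridden.
#' @param profile Numeric vector of precipitation multipliers, recycled over
#'   consecutive blocks of `profile_months` months (default 24, one census
#'   interval per block). `NULL` means all ones.
#' @param profile_months Block length in months for `profile`.
#' @param seed Optional integer seed.
#'
#' @details Baseline parameters: `tmean_annual` (6.4 C), `tamp` (10 C seasonal
#'   half-amplitude), `tnoise_sd` (0.8 C), `trange` (7 C mean diurnal range),
#'   `precip_mean` (440 mm/month), `precip_seasonal` (0.6 relative summer
#'   excess), `precip_shape` (gamma shape 1.5), `rh_mean` (75), `rh_sd` (6),
#'   `wind_mean` (3 m/s), `solar_mean` (14 MJ m-2 day-1), `solar_amp` (6).
#'
#' @return A tibble with columns `year`, `month`, `precip_mm`, `tmean_C`,
#'   `tmax_C`, `tmin_C`, `rh_pct`, `wind_ms`, `solar_MJ_m2_day`.
#' @examples
#' w <- simulate_weather(120, seed = 1)
#' dplyr::summarise(w, annual_precip = 12 * mean(precip_mm))
#' @export
simulate_weather <- function(n_months, start_year = 2010,
                             baseline = list(), profile = NULL,
                             profile_months = 24, seed = NULL) {
  if (n_months < 48) {
    rlang::abort("n_months must be >= 48 (24-month window plus calibration data)")
  }
  base <- list(
    tmean_annual = 6.4, tamp = 10, tnoise_sd = 0.8, trange = 7,
    precip_mean = 440, precip_seasonal = 0.6, precip_shape = 1.5,
    rh_mean = 75, rh_sd = 6, wind_mean = 3,
    solar_mean = 14, solar_amp = 6
  )
  base[names(baseline)] <- baseline
  run <- function() {
    i <- seq_len(n_months)
    month <- ((i - 1L) %% 12L) + 1L
    year <- start_year + (i - 1L) %/% 12L
    phase <- 2 * pi * (month - 7) / 12  # peak in July
    tmean <- base$tmean_annual + base$tamp * cos(phase) +
      stats::rnorm(n_months, 0, base$tnoise_sd)
    tmax <- tmean + base$trange / 2
    tmin <- tmean - base$trange / 2
    mult <- if (is.null(profile)) rep(1, n_months) else {
      blk <- ((i - 1L) %/% profile_months) %% length(profile) + 1L
      profile[blk]
    }
    pr_mean <- base$precip_mean * (1 + base$precip_seasonal * cos(phase)) * mult
    precip <- ifelse(pr_mean <= 0, 0,
                     stats::rgamma(n_months, shape = base$precip_shape,
                                   scale = pmax(pr_mean, 1e-12) / base$precip_shape))
    rh <- pmin(pmax(stats::rnorm(n_months, base$rh_mean, base$rh_sd), 5), 100)
    wind <- pmax(stats::rnorm(n_months, base$wind_mean, 0.5), 0.1)
    solar <- pmax(base$solar_mean + base$solar_amp * cos(phase) +
                    stats::rnorm(n_months, 0, 1), 0.5)
    tibble::tibble(
      year = year, month = month, precip_mm = precip,
      tmean_C = tmean, tmax_C = tmax, tmin_C = tmin,
      rh_pct = rh, wind_ms = wind, solar_MJ_m2_day = solar
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
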