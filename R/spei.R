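DAYS_IN_MONTH <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

# saturation vapour pressure (kPa) at temperature T (deg C)
svp <- function(T) 0.6108 * exp(17.27 * T / (T + 237.3))

#' Monthly FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Computes reference evapotranspiration (mm/month) from monthly means of
#' temperature, humidity, wind speed and solar radiation, using the FAO-56
#' Penman-Monteith formulation with extraterrestrial and clear-sky radiation
#' derived from latitude and the mid-month day of year. Soil heat flux is
#' taken as zero at the monthly scale; daily reference evapotranspiration is
#' floored at zero before scaling by days in month.
#'
#' @param weather Monthly weather tibble (see [simulate_weather()]) with
#'   columns `year`, `month`, `tmean_C`, `tmax_C`, `tmin_C`, `rh_pct`,
#'   `wind_ms`, `solar_MJ_m2_day`.
#' @param latitude Site latitude in decimal degrees (within \[-90, 90\]).
#' @param elevation Site elevation (m).
#' @return Numeric vector of monthly reference evapotranspiration (mm).
#' @export
pet_fao56 <- function(weather, latitude, elevation = 0) {
  need <- c("month", "tmean_C", "tmax_C", "tmin_C", "rh_pct", "wind_ms",
            "solar_MJ_m2_day")
  missing <- setdiff(need, names(weather))
  if (length(missing) > 0) {
    rlang::abort(paste0("weather is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (abs(latitude) > 90) rlang::abort("latitude must lie in [-90, 90]")
  T <- weather$tmean_C
  u2 <- weather$wind_ms
  Rs <- weather$solar_MJ_m2_day
  es <- (svp(weather$tmax_C) + svp(weather$tmin_C)) / 2
  ea <- pmin(weather$rh_pct, 100) / 100 * es
  delta <- 4098 * svp(T) / (T + 237.3)^2
  P_atm <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  gamma <- 0.000665 * P_atm
  # mid-month day of year
  J <- cumsum(DAYS_IN_MONTH) - DAYS_IN_MONTH / 2
  J <- J[weather$month]
  phi <- latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  decl <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  ws <- acos(pmin(pmax(-tan(phi) * tan(decl), -1), 1))
  Ra <- (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  Rso <- (0.75 + 2e-5 * elevation) * Ra
  Rns <- (1 - 0.23) * Rs
  tk4 <- ((weather$tmax_C + 273.16)^4 + (weather$tmin_C + 273.16)^4) / 2
  # clear-sky fraction bounded as in standard practice; keeps the net
  # longwave term physical when a month records (near) zero radiation
  rel_sun <- ifelse(Rso > 0, pmin(pmax(Rs / Rso, 0.33), 1), 0.33)
  Rnl <- 4.903e-9 * tk4 * (0.34 - 0.14 * sqrt(pmax(ea, 0))) *
    (1.35 * rel_sun - 0.35)
  Rn <- Rns - Rnl
  et0_day <- (0.408 * delta * Rn + gamma * (900 / (T + 273)) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
  pmax(et0_day, 0) * DAYS_IN_MONTH[weather$month]
}

#' Monthly climatic water balance D = P - PET
#'
#' @inheritParams pet_fao56
#' @return The input tibble with added columns `pet_mm` and `D_mm`.
#' @export
water_balance <- function(weather, latitude, elevation = 0) {
  pet <- pet_fao56(weather, latitude, elevation)
  dplyr::mutate(weather, pet_mm = pet, D_mm = .data$precip_mm - pet)
}

#' Trailing rolling sums of a monthly series
#'
#' @param x Numeric series.
#' @param window Window length (default 24 months); the first `window - 1`
#'   positions are `NA`.
#' @return Numeric vector, same length as `x`.
#' @export
rolling_sum <- function(x, window = 24) {
  if (length(x) < window) rlang::abort("series shorter than the window")
  zoo::rollsumr(x, k = window, fill = NA)
}

#' Fit a three-parameter log-logistic (Fisk) distribution
#'
#' Default method is L-moments via unbiased probability-weighted moments (the
#' standard choice for drought-index standardisation at modest sample sizes);
#' maximum likelihood is available as an alternative.
#'
#' @param x Numeric sample (>= 30 values, not all equal).
#' @param method `"lmoments"` (default) or `"mle"`.
#' @return A `fir_fisk` list with `shape`, `scale`, `location`, `method`.
#' @export
fit_fisk <- function(x, method = c("lmoments", "mle")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 30) rlang::abort("need >= 30 finite values")
  if (stats::sd(x) == 0) rlang::abort("degenerate (constant) input")
  fit <- if (method == "lmoments") fisk_lmom(x) else fisk_mle(x)
  if (fit$location > min(x)) {
    rlang::warn("fitted location exceeds the sample minimum; CDF is clipped there")
  }
  structure(c(fit, list(method = method)), class = "fir_fisk")
}

fisk_lmom <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  i <- seq_len(n)
  # unbiased probability-weighted moments with decreasing weights (1 - F)^s,
  # the parameterisation the drought-index literature states the fit in
  b0 <- mean(xs)
  b1 <- sum((i - 1) / (n - 1) * xs) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * xs) / n
  w0 <- b0
  w1 <- b0 - b1
  w2 <- b0 - 2 * b1 + b2
  shape <- (2 * w1 - w0) / (6 * w1 - w0 - 6 * w2)
  if (!is.finite(shape) || shape <= 1) {
    # L-moment solution invalid (needs shape > 1 for a finite mean); fall back
    return(fisk_mle(x))
  }
  g12 <- gamma(1 + 1 / shape) * gamma(1 - 1 / shape)
  scale <- (w0 - 2 * w1) * shape / g12
  location <- w0 - scale * g12
  list(shape = shape, scale = scale, location = location)
}

fisk_mle <- function(x) {
  nll <- function(th) {
    shape <- exp(th[1]); scale <- exp(th[2])
    loc <- min(x) - exp(th[3])
    z <- (x - loc) / scale
    -sum(log(shape / scale) + (shape - 1) * log(z) - 2 * log1p(z^shape))
  }
  s0 <- stats::sd(x)
  opt <- stats::optim(c(log(2), log(s0), log(s0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  list(shape = exp(opt$par[1]), scale = exp(opt$par[2]),
       location = min(x) - exp(opt$par[3]))
}

#' Fisk cumulative distribution function
#'
#' @param q Quantiles.
#' @param fit A `fir_fisk`.
#' @return CDF values in \[0, 1\].
#' @export
pfisk <- function(q, fit) {
  z <- (q - fit$location) / fit$scale
  ifelse(z <= 0, 0, 1 / (1 + z^(-fit$shape)))
}

#' Map water-balance sums to standard-normal SPEI values
#'
#' `SPEI = qnorm(F_fisk(sum))`, with CDF values clipped to
#' `[1e-6, 1 - 1e-6]` before inversion.
#'
#' @param sums Rolling water-balance sums (NA allowed).
#' @param fit A `fir_fisk`.
#' @return Numeric SPEI values.
#' @export
spei_transform <- function(sums, fit) {
  p <- pmin(pmax(pfisk(sums, fit), 1e-6), 1 - 1e-6)
  out <- stats::qnorm(p)
  out[!is.finite(sums)] <- NA_real_
  out
}

#' Standardised precipitation-evapotranspiration index from monthly weather
#'
#' Full SPEI pipeline: FAO-56 reference evapotranspiration, monthly water
#' balance `D = P - PET`, trailing `window`-month sums, a log-logistic (Fisk)
#' fit to the pooled sums over the whole series (the calibration period), and
#' standard-normal transformation of the fitted CDF.
#'
#' @inheritParams pet_fao56
#' @param window Accumulation window in months (default 24).
#' @param method Fisk fitting method, see [fit_fisk()].
#' @return A `fir_spei` tibble with `year`, `month`, `D_mm`, `D_sum`, `spei`;
#'   the Fisk fit is attached as attribute `"fisk_fit"`.
#' @examples
#' w <- simulate_weather(120, seed = 1)
#' s <- spei(w, latitude = 33.36, elevation = 1650)
#' mean(s$spei, na.rm = TRUE)
#' @export
spei <- function(weather, latitude, elevation = 0, window = 24,
                 method = c("lmoments", "mle")) {
  wb <- water_balance(weather, latitude, elevation)
  sums <- rolling_sum(wb$D_mm, window)
  fit <- fit_fisk(sums[is.finite(sums)], method = match.arg(method))
  out <- tibble::tibble(
    year = wb$year, month = wb$month, D_mm = wb$D_mm, D_sum = sums,
    spei = spei_transform(sums, fit)
  )
  attr(out, "fisk_fit") <- fit
  class(out) <- c("fir_spei", class(out))
  out
}

#' Per-census-interval drought values from a monthly SPEI series
#'
#' The default reading takes the SPEI value at each interval's end month: with
#' a 24-month accumulation window that value already integrates the two-year
#' interval. An alternative averages the monthly SPEI values over the
#' interval's months.
#'
#' @param spei_series A `fir_spei` tibble (or any tibble with `year`, `month`,
#'   `spei`).
#' @param ends A data frame with columns `year` and `month` giving each
#'   interval's end month (one row per interval), and optionally `interval`
#'   labels.
#' @param method `"end"` (default) or `"mean_monthly"`.
#' @param span_months Interval length used by `"mean_monthly"` (default 24).
#' @return A tibble with `interval`, `year`, `month`, `spei`.
#' @export
interval_spei <- function(spei_series, ends,
                          method = c("end", "mean_monthly"),
                          span_months = 24) {
  method <- match.arg(method)
  idx_of <- function(y, m) which(spei_series$year == y & spei_series$month == m)
  vals <- purrr::map2_dbl(ends$year, ends$month, function(y, m) {
    i <- idx_of(y, m)
    if (length(i) != 1) rlang::abort("interval end month not found in the SPEI series")
    if (method == "end") {
      spei_series$spei[i]
    } else {
      lo <- max(1L, i - span_months + 1L)
      mean(spei_series$spei[lo:i], na.rm = TRUE)
    }
  })
  tibble::tibble(
    interval = if ("interval" %in% names(ends)) ends$interval else seq_len(nrow(ends)),
    year = ends$year, month = ends$month, spei = vals
  )
}

#' @export
print.fir_fisk <- function(x, ...) {
  cat(sprintf("Fisk fit (%s): shape %.3f, scale %.3f, location %.3f\n",
              x$method, x$shape, x$scale, x$location))
  invisible(x)
}
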