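test_that("reference evapotranspiration matches an independent hand computation", {
  # one June month: tmean 20 C (no diurnal range), rh 60%, wind 2 m/s,
  # solar 15 MJ m-2 d-1, sea level, latitude 35 N
  w <- tibble::tibble(year = 2000, month = 6, precip_mm = 0,
                      tmean_C = 20, tmax_C = 20, tmin_C = 20,
                      rh_pct = 60, wind_ms = 2, solar_MJ_m2_day = 15)
  pet <- pet_fao56(w, latitude = 35, elevation = 0)
  # line-by-line FAO-56 arithmetic, written out independently
  es <- 0.6108 * exp(17.27 * 20 / (20 + 237.3))        # 2.3385 kPa
  ea <- 0.6 * es
  delta <- 4098 * es / (20 + 237.3)^2                  # 0.14474 kPa/C
  gamma <- 0.000665 * 101.3                            # 0.06736 kPa/C
  J <- 181 - 15                                        # mid-June day of year
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  decl <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  phi <- 35 * pi / 180
  ws <- acos(-tan(phi) * tan(decl))
  Ra <- 24 * 60 / pi * 0.082 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  Rso <- 0.75 * Ra
  Rns <- 0.77 * 15
  Rnl <- 4.903e-9 * (293.16^4) * (0.34 - 0.14 * sqrt(ea)) *
    (1.35 * min(15 / Rso, 1) - 0.35)
  Rn <- Rns - Rnl
  et0 <- (0.408 * delta * Rn + gamma * 900 / (20 + 273) * 2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * 2)) * 30
  expect_lt(abs(pet - et0), 0.5)
  expect_gt(pet, 50)  # a warm humid month evaporates on the order of 100 mm
})

test_that("evapotranspiration is zero without energy and rises with wind", {
  dark <- tibble::tibble(year = 2000, month = 1, precip_mm = 0,
                         tmean_C = 5, tmax_C = 5, tmin_C = 5,
                         rh_pct = 100, wind_ms = 0, solar_MJ_m2_day = 0)
  expect_equal(pet_fao56(dark, 35, 0), 0)
  breezy <- tibble::tibble(year = 2000, month = 7, precip_mm = 0,
                           tmean_C = 18, tmax_C = 24, tmin_C = 12,
                           rh_pct = 55, wind_ms = c(2, 4), solar_MJ_m2_day = 16)
  pets <- pet_fao56(breezy, 35, 100)
  expect_gt(pets[2], pets[1])
  expect_error(pet_fao56(dark, 95, 0), "latitude")
  expect_error(pet_fao56(dplyr::select(dark, -"wind_ms"), 35, 0), "missing")
})

test_that("rolling sums match a brute-force loop", {
  set.seed(12)
  x <- rnorm(100)
  rs <- rolling_sum(x, 24)
  expect_true(all(is.na(rs[1:23])))
  for (i in c(24, 50, 100)) expect_equal(rs[i], sum(x[(i - 23):i]))
  expect_equal(rolling_sum(rep(2.5, 30), 24)[24:30], rep(60, 7))
  expect_equal(rolling_sum(x, 1), x)
  expect_error(rolling_sum(x[1:10], 24), "shorter")
  # first differences of the rolling series telescope exactly
  d <- diff(rs[24:100])
  expect_equal(d, x[25:100] - x[1:76])
})

test_that("Fisk fit recovers known parameters and centres the CDF", {
  set.seed(14)
  u <- runif(2000)
  x <- -50 + 100 * (u / (1 - u))^(1 / 3)  # Fisk(shape 3, scale 100, loc -50)
  fit <- fit_fisk(x)
  expect_lt(abs(fit$shape - 3) / 3, 0.1)
  expect_lt(abs(fit$scale - 100) / 100, 0.1)
  expect_lt(abs(fit$location - (-50)) / 50, 0.2)
  expect_lte(fit$location, min(x))
  expect_lt(abs(pfisk(median(x), fit) - 0.5), 0.05)
  # maximum likelihood route lands in the same place
  fit_ml <- fit_fisk(x, method = "mle")
  expect_lt(abs(fit_ml$shape - 3) / 3, 0.1)
  expect_error(fit_fisk(rep(1, 50)), "degenerate")
  expect_error(fit_fisk(x[1:10]), ">= 30")
})

test_that("the standard-normal transform is centred and Gaussian-consistent", {
  set.seed(15)
  sums <- rnorm(400, 100, 30)
  fit <- fit_fisk(sums)
  z <- spei_transform(sums, fit)
  # the fitted median maps to zero
  expect_equal(spei_transform(fit$location + fit$scale, fit), 0, tolerance = 1e-10)
  expect_gt(cor(z, (sums - mean(sums)) / sd(sums)), 0.99)
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.85); expect_lt(sd(z), 1.15)
})

test_that("the index is invariant to a constant shift of the water balance", {
  set.seed(16)
  D <- rnorm(150, -20, 40)
  s1 <- rolling_sum(D, 24); s1 <- s1[is.finite(s1)]
  s2 <- rolling_sum(D + 7, 24); s2 <- s2[is.finite(s2)]
  z1 <- spei_transform(s1, fit_fisk(s1))
  z2 <- spei_transform(s2, fit_fisk(s2))
  expect_lt(max(abs(z1 - z2)), 1e-6)
})

test_that("the full pipeline standardises simulated mountain weather", {
  w <- simulate_weather(180, seed = 19)
  s <- spei(w, latitude = 33.36, elevation = 1650)
  expect_equal(nrow(s), 180)
  expect_true(all(is.na(s$spei[1:23])))
  z <- s$spei[!is.na(s$spei)]
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.85); expect_lt(sd(z), 1.15)
  # PET is nonnegative everywhere, the balance may not be
  expect_true(all(water_balance(w, 33.36, 1650)$pet_mm >= 0))
})

test_that("only a wet census interval gets a positive drought value", {
  # three normal-climate spin-up blocks calibrate the index; the census
  # blocks are dry except one wet (1.4x precipitation) interval. Low monthly
  # precipitation noise (gamma shape 12) keeps the constructed signal
  # identifiable: at the generator default the dry deficit is ~1.5 SD of the
  # 24-month sampling noise and the sign pattern is not a valid oracle.
  w <- simulate_weather(168, baseline = list(precip_shape = 12),
                        profile = c(1, 1, 1, 0.8, 1.4, 0.8, 0.85),
                        profile_months = 24, seed = 23)
  s <- spei(w, latitude = 33.36, elevation = 1650)
  ends <- tibble::tibble(
    interval = 1:4,
    year = s$year[c(96, 120, 144, 168)],
    month = s$month[c(96, 120, 144, 168)]
  )
  vals <- interval_spei(s, ends)
  expect_gt(vals$spei[2], 0)          # the 1.4-multiplier block
  expect_true(all(vals$spei[c(1, 3, 4)] < 0))
  # shifting the census grid by one month moves values continuously
  ends_shift <- dplyr::mutate(ends, year = s$year[c(95, 119, 143, 167)],
                              month = s$month[c(95, 119, 143, 167)])
  vals_shift <- interval_spei(s, ends_shift)
  max_step <- max(abs(diff(s$spei)), na.rm = TRUE)
  expect_lt(max(abs(vals$spei - vals_shift$spei)), max_step + 1e-12)
  # the mean-monthly alternative agrees in sign here
  vals_mean <- interval_spei(s, ends, method = "mean_monthly")
  expect_gt(vals_mean$spei[2], 0)
  expect_error(interval_spei(s, tibble::tibble(year = 1900, month = 1)), "not found")
})
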