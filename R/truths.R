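#' Published vital-rate parameter sets for the four biennial census intervals
#'
#' Returns the fitted vital-rate parameters for the monitored fir population,
#' one row per two-year census interval (2016--2024): survival logistic
#' coefficients (logit scale), growth linear-regression coefficients and
#' residual SD (cm), and the observed per-capita recruitment rate per
#' interval. These parameter sets drive the synthetic census generator and
#' the worked kernel examples.
#'
#' @return A tibble with columns `interval`, `surv_intercept`, `surv_slope`,
#'   `growth_intercept`, `growth_slope`, `growth_sd`, `recruitment_rate`.
#'   `growth_sd` is the residual standard deviation (the square root of the
#'   published residual variance).
#' @examples
#' vital_rate_truths()
#' @export
vital_rate_truths <- function() {
  tibble::tibble(
    interval         = c("2016-2018", "2018-2020", "2020-2022", "2022-2024"),
    surv_intercept   = c(3.345, 3.64, 5.38, 3.84),
    surv_slope       = c(0.005, 0.033, 0.032, 0.001),
    growth_intercept = c(0.27, 0.303, 0.272, 0.323),
    growth_slope     = c(1.007, 1.005, 1.003, 1.004),
    growth_sd        = sqrt(c(0.339, 0.301, 0.246, 0.287)),
    recruitment_rate = c(0.018, 0.034, 0.006, 0.002)
  )
}

validate_truths <- function(truths) {
  stopifnot(is.data.frame(truths))
  required <- c("interval", "surv_intercept", "surv_slope", "growth_intercept",
                "growth_slope", "growth_sd", "recruitment_rate")
  missing <- setdiff(required, names(truths))
  if (length(missing) > 0) {
    rlang::abort(paste0("truths is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(truths$growth_sd <= 0)) rlang::abort("growth_sd must be > 0")
  if (any(truths$recruitment_rate < 0 | truths$recruitment_rate >= 1)) {
    rlang::abort("recruitment_rate must lie in [0, 1)")
  }
  if (anyDuplicated(truths$interval)) rlang::abort("interval labels must be unique")
  invisible(truths)
}
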