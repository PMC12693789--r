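#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a projection kernel as a heat map
#'
#' @param object A `fir_kernel`.
#' @param which Which matrix to draw (`"K"`, `"P"` or `"F"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fir_kernel
#' @export
autoplot.fir_kernel <- function(object, which = c("K", "P", "F"), ...) {
  which <- match.arg(which)
  M <- object[[which]]
  mid <- if (!is.null(object$grid)) object$grid$mid else seq_len(nrow(M))
  df <- tidyr::expand_grid(y = mid, x = mid)
  df$value <- as.vector(M)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "size at t (cm)", y = "size at t+1 (cm)",
                  fill = which,
                  title = sprintf("%s kernel (lambda = %.3f)", which, object$lambda)) +
    ggplot2::theme_minimal()
}

#' Plot a posterior lambda ensemble
#'
#' @param object A `fir_lambda_ensemble`.
#' @param ... Unused.
#' @return A ggplot histogram with the ensemble mean and the mean-kernel
#'   lambda marked.
#' @method autoplot fir_lambda_ensemble
#' @export
autoplot.fir_lambda_ensemble <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda)
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$lambda_mean_kernel,
                        colour = "steelblue", linetype = 2) +
    ggplot2::labs(x = "population growth rate per interval", y = "draws") +
    ggplot2::theme_minimal()
}

#' Plot size-specific elasticity profiles
#'
#' @param object A `fir_elasticity` tibble (possibly row-bound over vital
#'   rates).
#' @param ... Unused.
#' @return A ggplot of elasticity against diameter.
#' @method autoplot fir_elasticity
#' @export
autoplot.fir_elasticity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$midpoint, .data$elasticity,
                                       colour = .data$vital_rate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DBH (cm)", y = "elasticity of lambda",
                  colour = "vital rate") +
    ggplot2::theme_minimal()
}

#' Plot SHAP importance of vital-rate parameters
#'
#' @param object A `fir_importance`.
#' @param ... Unused.
#' @return A ggplot bar chart of mean absolute SHAP values.
#' @method autoplot fir_importance
#' @export
autoplot.fir_importance <- function(object, ...) {
  df <- object$importance
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_abs_shap,
                                   stats::reorder(.data$parameter, .data$mean_abs_shap))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean |SHAP| (lambda units)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the drought regression with interval uncertainty
#'
#' @param object A `fir_regression`.
#' @param ... Unused.
#' @return A ggplot of observed log lambda (with observation-error bars)
#'   against the standardised drought index, with the posterior-mean line.
#' @method autoplot fir_regression
#' @export
autoplot.fir_regression <- function(object, ...) {
  s <- tidy(object)
  a <- s$estimate[s$parameter == "alpha"]
  b <- s$estimate[s$parameter == "beta"]
  ggplot2::ggplot(object$data, ggplot2::aes(.data$x_std, .data$y_hat)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y_hat - 2 * .data$sigma_obs,
                                        ymax = .data$y_hat + 2 * .data$sigma_obs),
                           width = 0.05, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = a, slope = b, colour = "firebrick") +
    ggplot2::labs(x = "standardised SPEI-24", y = "log lambda") +
    ggplot2::theme_minimal()
}

#' Plot projected size structures
#'
#' @param projection A tibble from [project_population()].
#' @param steps Which steps to draw (default: all).
#' @return A ggplot of counts against diameter, one line per projected step.
#' @export
plot_projection <- function(projection, steps = NULL) {
  df <- projection
  if (!is.null(steps)) df <- dplyr::filter(df, .data$step %in% steps)
  xvar <- if ("midpoint" %in% names(df)) "midpoint" else "cell"
  grp <- if ("year" %in% names(df)) "year" else "step"
  ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$count,
                                   colour = factor(.data[[grp]]))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DBH (cm)", y = "individuals", colour = grp) +
    ggplot2::theme_minimal()
}
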