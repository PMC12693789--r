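#' Monte-Carlo dataset mapping vital-rate parameters to lambda
#'
#' Draws joint samples of the six core parameters (survival intercept and
#' slope, growth intercept, slope and SD, recruitment rate) from their
#' posteriors, assembles the full kernel for each sample and records its
#' dominant eigenvalue. The result is the training set for the
#' gradient-boosted surrogate used in SHAP importance analysis.
#'
#' @inheritParams lambda_ensemble
#' @param n Number of Monte-Carlo samples (default 1000).
#' @return A `fir_lambda_dataset` tibble: the six parameter columns and
#'   `lambda`.
#' @export
lambda_dataset <- function(surv, growth, R, grid, fc = fecundity_config(),
                           n = 1000, seed = NULL) {
  ens <- lambda_ensemble(surv, growth, R, grid, fc, n_draws = n, seed = seed)
  out <- dplyr::bind_cols(ens$params, tibble::tibble(lambda = ens$lambda))
  class(out) <- c("fir_lambda_dataset", class(out))
  out
}

#' Gradient-boosted surrogate of the parameter-to-lambda map
#'
#' Fits a boosted-tree regressor (500 trees, depth 3, learning rate 0.05)
#' of lambda on the sampled parameters, holding out 20% of rows to measure
#' fit quality. The surrogate is refused (error) when the held-out R-squared
#' falls below `min_r2`, since SHAP values of an unfaithful surrogate are
#' meaningless.
#'
#' @param data A `fir_lambda_dataset` (or data frame with a `lambda` column
#'   and numeric predictors; >= 100 rows).
#' @param min_r2 Minimum held-out R-squared (default 0.7).
#' @param nrounds,max_depth,eta Boosting hyperparameters.
#' @param seed Seed controlling the train/test split and boosting.
#' @return A `fir_surrogate` list with the fitted `booster`, `r2`, feature
#'   names and the split.
#' @export
fit_surrogate <- function(data, min_r2 = 0.7, nrounds = 500, max_depth = 3,
                          eta = 0.05, seed = 1) {
  if (nrow(data) < 100) rlang::abort("need >= 100 rows to fit the surrogate")
  if (!"lambda" %in% names(data)) rlang::abort("data must have a lambda column")
  if (stats::var(data$lambda) == 0) {
    rlang::abort("lambda is constant; surrogate R-squared is undefined")
  }
  features <- setdiff(names(data), "lambda")
  X <- as.matrix(data[features])
  # centre the response: boosting accumulates leaf values in single
  # precision, so keeping them near zero preserves additivity to ~1e-8
  offset <- mean(data$lambda)
  y <- data$lambda - offset
  run <- function() {
    n <- nrow(X)
    test <- sample.int(n, max(1L, floor(0.2 * n)))
    booster <- xgboost::xgboost(
      X[-test, , drop = FALSE], y[-test],
      nrounds = nrounds, max_depth = max_depth, learning_rate = eta,
      objective = "reg:squarederror", nthreads = 1, verbosity = 0
    )
    pred <- stats::predict(booster, X[test, , drop = FALSE])
    r2 <- 1 - sum((y[test] - pred)^2) / sum((y[test] - mean(y[test]))^2)
    list(booster = booster, r2 = r2, test_rows = test)
  }
  fit <- withr::with_seed(seed, run())
  if (fit$r2 < min_r2) {
    rlang::abort(sprintf(
      "surrogate held-out R-squared %.3f is below %.2f; refusing SHAP analysis",
      fit$r2, min_r2))
  }
  structure(
    list(booster = fit$booster, r2 = fit$r2, features = features,
         test_rows = fit$test_rows, X = X, offset = offset),
    class = "fir_surrogate"
  )
}

#' @export
predict.fir_surrogate <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$X
  if (is.data.frame(newdata)) newdata <- as.matrix(newdata[object$features])
  stats::predict(object$booster, newdata) + object$offset
}

#' SHAP importance of vital-rate parameters for lambda
#'
#' Computes exact TreeSHAP contributions of every parameter for every sampled
#' row of the surrogate's training matrix. Importance is the mean absolute
#' SHAP value per parameter; per-row additivity (bias + contributions =
#' prediction) is checked and reported.
#'
#' @param surrogate A `fir_surrogate`.
#' @param X Optional matrix of rows to explain (default: the surrogate's own
#'   training matrix).
#' @return A `fir_importance` list: `importance` tibble (parameter,
#'   `mean_abs_shap`, `rank`), per-row `shap` matrix, `bias`, and
#'   `max_additivity_error`.
#' @export
shap_importance <- function(surrogate, X = NULL) {
  if (is.null(X)) X <- surrogate$X
  contrib <- stats::predict(surrogate$booster, X, type = "contrib")
  bias <- contrib[, ncol(contrib)] + surrogate$offset
  shap <- contrib[, -ncol(contrib), drop = FALSE]
  colnames(shap) <- surrogate$features
  pred <- stats::predict(surrogate$booster, X) + surrogate$offset
  add_err <- max(abs(bias + rowSums(shap) - pred))
  imp <- tibble::tibble(
    parameter = colnames(shap),
    mean_abs_shap = colMeans(abs(shap))
  )
  imp <- dplyr::arrange(imp, dplyr::desc(.data$mean_abs_shap))
  imp$rank <- seq_len(nrow(imp))
  structure(
    list(importance = imp, shap = shap, bias = bias,
         max_additivity_error = add_err, r2 = surrogate$r2),
    class = "fir_importance"
  )
}

#' @describeIn shap_importance Importance table.
#' @param x A `fir_importance`.
#' @param ... Unused.
#' @method tidy fir_importance
#' @export
tidy.fir_importance <- function(x, ...) x$importance

#' Kernel-entry elasticities from the eigenvector sensitivity formula
#'
#' The sensitivity of lambda to entry `K[i, j]` is
#' `s_ij = v_i w_j / <v, w>` with `w`, `v` the dominant right and left
#' eigenvectors; the elasticity is `e_ij = (K_ij / lambda) * s_ij`.
#' Elasticities sum to one.
#'
#' @param kernel A `fir_kernel` or nonnegative square matrix.
#' @return List with matrices `sensitivity` and `elasticity`, plus `lambda`.
#' @export
kernel_elasticity <- function(kernel) {
  if (inherits(kernel, "fir_kernel")) {
    K <- kernel$K; eig <- list(lambda = kernel$lambda, w = kernel$w, v = kernel$v)
  } else {
    K <- kernel; eig <- dominant_eigen(K)
  }
  s <- outer(eig$v, eig$w) / sum(eig$v * eig$w)
  list(sensitivity = s, elasticity = (K / eig$lambda) * s, lambda = eig$lambda)
}

# rebuild column j of P with survival multiplied by (1 + delta), capped at 1
perturb_survival_column <- function(kernel, params, j, delta) {
  p <- as_params(params)
  x <- kernel$grid$mid
  g <- growth_column(p$growth_intercept + p$growth_slope * x[j], p$growth_sd,
                     kernel$grid)
  s <- stats::plogis(p$surv_intercept + p$surv_slope * x[j])
  K <- kernel$K
  K[, j] <- kernel$F[, j] + g * min(s * (1 + delta), 1)
  K
}

#' Size-specific elasticity of lambda to survival
#'
#' Perturbs survival one diameter class at a time (multiplying the class's
#' survival probability by `1 + delta`, capped at one), rebuilds that column
#' of the survival-growth kernel, recomputes lambda, and scales the response:
#' `e_j = (delta lambda / lambda) / delta`. A Richardson consistency value at
#' `delta / 2` is included.
#'
#' @param kernel A `fir_kernel` built by [ipm_kernel()].
#' @param params The vital-rate parameters the kernel was built from.
#' @param delta Relative perturbation (default 1e-4).
#' @return A `fir_elasticity` tibble: `midpoint`, `elasticity`,
#'   `elasticity_half_delta`, `vital_rate = "survival"`.
#' @export
survival_elasticity <- function(kernel, params, delta = 1e-4) {
  lam0 <- kernel$lambda
  one <- function(d) {
    vapply(seq_len(kernel$grid$n), function(j) {
      (dominant_eigen(perturb_survival_column(kernel, params, j, d))$lambda - lam0) /
        (lam0 * d)
    }, numeric(1))
  }
  out <- tibble::tibble(
    midpoint = kernel$grid$mid,
    elasticity = one(delta),
    elasticity_half_delta = one(delta / 2),
    vital_rate = "survival"
  )
  class(out) <- c("fir_elasticity", class(out))
  out
}

#' Size-specific elasticity of lambda to the growth mean
#'
#' Shifts the mean of the growth distribution at one diameter class at a time
#' by a relative `delta` (the class's mean growth target is multiplied by
#' `1 + delta`), rebuilds that column with eviction renormalisation,
#' recomputes lambda, and scales as in [survival_elasticity()].
#'
#' @inheritParams survival_elasticity
#' @return A `fir_elasticity` tibble with `vital_rate = "growth_mean"`.
#' @export
growth_elasticity <- function(kernel, params, delta = 1e-4) {
  p <- as_params(params)
  x <- kernel$grid$mid
  lam0 <- kernel$lambda
  one <- function(d) {
    vapply(seq_len(kernel$grid$n), function(j) {
      mu <- (p$growth_intercept + p$growth_slope * x[j]) * (1 + d)
      g <- growth_column(mu, p$growth_sd, kernel$grid)
      s <- stats::plogis(p$surv_intercept + p$surv_slope * x[j])
      K <- kernel$K
      K[, j] <- kernel$F[, j] + g * s
      (dominant_eigen(K)$lambda - lam0) / (lam0 * d)
    }, numeric(1))
  }
  out <- tibble::tibble(
    midpoint = x,
    elasticity = one(delta),
    elasticity_half_delta = one(delta / 2),
    vital_rate = "growth_mean"
  )
  class(out) <- c("fir_elasticity", class(out))
  out
}

#' Relative sensitivity of lambda to a fecundity-kernel constant
#'
#' Central finite difference of lambda with respect to one fecundity constant
#' (`beta_alpha`, `beta_beta` or `threshold`), as a relative sensitivity
#' `(delta lambda / lambda) / (delta theta / theta)`. The kernel is rebuilt
#' from a list of per-interval parameter sets and averaged (the time-averaged
#' kernel) at each perturbed value; pass a single parameter set for a
#' single-interval kernel.
#'
#' @param params_list A data frame of vital-rate parameter rows (one per
#'   interval) including `recruitment_rate`, or a single-row set.
#' @param grid A [size_grid()].
#' @param fc A [fecundity_config()].
#' @param param One of `"beta_alpha"`, `"beta_beta"`, `"threshold"`.
#' @param rel_delta Relative perturbation (default 0.01).
#' @return The relative sensitivity (scalar).
#' @export
fecundity_sensitivity <- function(params_list, grid, fc = fecundity_config(),
                                  param = c("beta_alpha", "beta_beta", "threshold"),
                                  rel_delta = 0.01) {
  param <- match.arg(param)
  theta <- fc[[param]]
  if (theta <= 0) rlang::abort("perturbed parameter must be strictly positive")
  lam_at <- function(value) {
    fc2 <- fc
    fc2[[param]] <- value
    ks <- lapply(seq_len(nrow(params_list)), function(i) {
      ipm_kernel(params_list[i, ], grid, fc2)
    })
    mean_kernel(ks)$lambda
  }
  lam0 <- lam_at(theta)
  lam_hi <- lam_at(theta * (1 + rel_delta))
  lam_lo <- lam_at(theta * (1 - rel_delta))
  ((lam_hi - lam_lo) / lam0) / (2 * rel_delta)
}

#' Sweep fecundity configurations for the printed-parameter worked examples
#'
#' Evaluates, for each combination of `m(x)` normalisation and recruit-window
#' mapping, the per-interval kernel eigenvalues and the mean-kernel
#' eigenvalue from a table of vital-rate parameter sets, plus the relative
#' sensitivities of lambda to the recruit-size Beta shapes and the
#' reproductive threshold. Documents how each configuration choice moves the
#' reproducibility of published point values.
#'
#' @param params A data frame of per-interval parameter rows (e.g.
#'   [vital_rate_truths()]).
#' @param grid A [size_grid()].
#' @param normalizations Character vector of `m_normalization` values.
#' @param windows Named list of recruit-window settings (`NULL` = below the
#'   threshold, `"full"` = whole grid).
#' @return A tibble with one row per configuration: per-interval lambdas,
#'   `lambda_mean`, `sens_alpha`, `sens_beta`, `sens_threshold`.
#' @export
fecundity_sweep <- function(params, grid,
                            normalizations = c("mean_one", "max_one", "none"),
                            windows = list(below_threshold = NULL, full = "full")) {
  purrr::map_dfr(normalizations, function(nm) {
    purrr::imap_dfr(windows, function(win, winlab) {
      fc <- fecundity_config(recruit_window = win, m_normalization = nm)
      ks <- lapply(seq_len(nrow(params)), function(i) ipm_kernel(params[i, ], grid, fc))
      lams <- vapply(ks, `[[`, numeric(1), "lambda")
      names(lams) <- paste0("lambda_", params$interval)
      dplyr::bind_cols(
        tibble::tibble(m_normalization = nm, recruit_window = winlab),
        tibble::as_tibble(as.list(lams)),
        tibble::tibble(
          lambda_mean = mean_kernel(ks)$lambda,
          sens_alpha = fecundity_sensitivity(params, grid, fc, "beta_alpha"),
          sens_beta = fecundity_sensitivity(params, grid, fc, "beta_beta"),
          sens_threshold = fecundity_sensitivity(params, grid, fc, "threshold")
        )
      )
    })
  })
}
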