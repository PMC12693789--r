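#' Discretisation grid for the size-structured kernel
#'
#' Builds the midpoint-rule mesh used to discretise the projection kernel.
#' Following the usual anti-eviction buffer, the lower bound is 90% of the
#' smallest observed diameter and the upper bound 110% of the largest, so that
#' growth draws rarely leave the modelled range.
#'
#' @param min_obs,max_obs Observed minimum and maximum diameter (cm).
#' @param n_mesh Number of mesh cells (default 100; must be >= 10).
#' @return A `fir_grid` list with `L`, `U`, `n`, `h` (cell width) and `mid`
#'   (cell midpoints).
#' @examples
#' g <- size_grid(3, 40)
#' c(g$L, g$U, g$h)
#' @export
size_grid <- function(min_obs, max_obs, n_mesh = 100) {
  if (!(min_obs > 0 && max_obs > min_obs)) {
    rlang::abort("need 0 < min_obs < max_obs")
  }
  if (n_mesh < 10) rlang::abort("n_mesh must be >= 10")
  L <- 0.9 * min_obs
  U <- 1.1 * max_obs
  h <- (U - L) / n_mesh
  structure(
    list(L = L, U = U, n = as.integer(n_mesh), h = h,
         mid = L + (seq_len(n_mesh) - 0.5) * h),
    class = "fir_grid"
  )
}

#' Fecundity kernel configuration
#'
#' The fecundity kernel is `F(y, x) = R * f_rec(y) * m(x)`: the per-capita
#' recruitment rate `R`, a Beta recruit-size distribution `f_rec`, and a
#' square-root size-dependent relative fecundity
#' `m(x) = (max(x - threshold, 0))^exponent` that is zero below the
#' reproductive threshold. `m` is defined only up to a constant; the
#' `m_normalization` flag fixes it:
#' \describe{
#'   \item{`"mean_one"`}{(default) scale `m` to mean 1 over mature grid cells,
#'     making `R` the mean per-capita recruit output of mature trees;}
#'   \item{`"max_one"`}{scale to maximum 1;}
#'   \item{`"none"`}{use the raw square root (proportionality constant 1).}
#' }
#'
#' @param beta_alpha,beta_beta Beta shape parameters of the recruit-size
#'   distribution (defaults 1.3 and 2).
#' @param threshold Reproductive threshold (cm, default 5).
#' @param exponent Fecundity size exponent (default 0.5).
#' @param recruit_window Diameter range (cm) the Beta distribution is mapped
#'   onto; `NULL` (default) means from the grid lower bound to the threshold,
#'   `"full"` maps onto the whole grid.
#' @param m_normalization One of `"mean_one"`, `"max_one"`, `"none"`.
#' @return A `fir_fecundity_config` list.
#' @export
fecundity_config <- function(beta_alpha = 1.3, beta_beta = 2, threshold = 5,
                             exponent = 0.5, recruit_window = NULL,
                             m_normalization = c("mean_one", "max_one", "none")) {
  if (beta_alpha <= 0 || beta_beta <= 0) rlang::abort("Beta shapes must be > 0")
  if (exponent <= 0) rlang::abort("exponent must be > 0")
  structure(
    list(beta_alpha = beta_alpha, beta_beta = beta_beta, threshold = threshold,
         exponent = exponent, recruit_window = recruit_window,
         m_normalization = match.arg(m_normalization)),
    class = "fir_fecundity_config"
  )
}

as_params <- function(params) {
  p <- as.list(params)
  need <- c("surv_intercept", "surv_slope", "growth_intercept", "growth_slope",
            "growth_sd")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing vital-rate parameters: ", paste(missing, collapse = ", ")))
  }
  if (p$growth_sd <= 0) rlang::abort("growth_sd must be > 0")
  p
}

#' Survival-growth kernel on a discretised grid
#'
#' Column `j` holds the normal growth transition from size `mid[j]`: the
#' growth density integrated over each destination cell (exact Gaussian cell
#' masses, accurate where the cell width is comparable to the growth SD),
#' renormalised to sum to one (the eviction correction: no probability mass
#' is lost outside the grid) and scaled by the survival probability
#' `plogis(surv_intercept + surv_slope * mid[j])`. Every column therefore sums
#' exactly to the size-specific survival probability.
#'
#' @param params Vital-rate parameters: a named list or one-row data frame
#'   with `surv_intercept`, `surv_slope`, `growth_intercept`, `growth_slope`,
#'   `growth_sd` (and optionally `recruitment_rate`).
#' @param grid A [size_grid()].
#' @return An `n x n` matrix.
#' @export
survival_growth_kernel <- function(params, grid) {
  p <- as_params(params)
  x <- grid$mid
  mu <- p$growth_intercept + p$growth_slope * x
  edges <- grid$L + (0:grid$n) * grid$h
  cdf <- outer(edges, mu, function(e, m) stats::pnorm(e, m, p$growth_sd))
  G <- cdf[-1, , drop = FALSE] - cdf[-(grid$n + 1L), , drop = FALSE]
  G <- sweep(G, 2, colSums(G), "/")
  sweep(G, 2, stats::plogis(p$surv_intercept + p$surv_slope * x), "*")
}

# one eviction-corrected growth column (sums to 1) for mean mu, sd sigma
growth_column <- function(mu, sigma, grid) {
  edges <- grid$L + (0:grid$n) * grid$h
  g <- diff(stats::pnorm(edges, mu, sigma))
  g / sum(g)
}

# recruit-size probability mass over the grid (sums to 1)
recruit_size_mass <- function(fc, grid) {
  win <- fc$recruit_window
  if (is.null(win)) win <- c(grid$L, fc$threshold)
  if (identical(win, "full")) win <- c(grid$L, grid$U)
  if (win[1] < grid$L - 1e-9 || win[2] > grid$U + 1e-9 || win[1] >= win[2]) {
    rlang::abort("recruit_window must lie within the grid with low < high")
  }
  x <- grid$mid
  u <- (x - win[1]) / diff(win)
  f <- ifelse(u > 0 & u < 1, stats::dbeta(u, fc$beta_alpha, fc$beta_beta), 0)
  if (sum(f) <= 0) rlang::abort("recruit size distribution has no mass on the grid")
  f / sum(f)
}

# relative fecundity m(x) under the configured normalisation
fecundity_m <- function(fc, grid) {
  if (fc$threshold <= grid$L || fc$threshold >= grid$U) {
    rlang::abort("reproductive threshold must lie inside the grid")
  }
  x <- grid$mid
  m <- pmax(x - fc$threshold, 0)^fc$exponent
  mature <- x > fc$threshold
  switch(fc$m_normalization,
    mean_one = m / mean(m[mature]),
    max_one  = m / max(m),
    none     = m
  )
}

#' Fecundity kernel on a discretised grid
#'
#' `F = R * outer(f_rec, m)`: recruit-size probability mass (columns are
#' per-capita recruit distributions summing to `R * m(x_j)`) times the
#' size-dependent relative fecundity. Columns at or below the reproductive
#' threshold are identically zero.
#'
#' @param R Per-capita recruitment rate per census interval (>= 0).
#' @param fc A [fecundity_config()].
#' @param grid A [size_grid()].
#' @return An `n x n` matrix.
#' @export
fecundity_kernel <- function(R, fc = fecundity_config(), grid) {
  if (R < 0) rlang::abort("R must be >= 0")
  if (fc$threshold <= grid$L || fc$threshold >= grid$U) {
    rlang::abort("reproductive threshold must lie inside the grid")
  }
  R * outer(recruit_size_mass(fc, grid), fecundity_m(fc, grid))
}

#' Assemble the full projection kernel K = P + F
#'
#' @param params Vital-rate parameters including `recruitment_rate` (used as
#'   `R` unless `R` is given explicitly).
#' @param grid A [size_grid()].
#' @param fc A [fecundity_config()].
#' @param R Optional explicit recruitment rate.
#' @return A `fir_kernel` list with matrices `P`, `F`, `K`, the `grid`, the
#'   fecundity config, `lambda`, and the dominant right (`w`, stable size
#'   structure) and left (`v`, reproductive value) eigenvectors, each
#'   normalised to sum to one.
#' @examples
#' g <- size_grid(3, 40)
#' k <- ipm_kernel(vital_rate_truths()[2, ], g)
#' k$lambda
#' @export
ipm_kernel <- function(params, grid, fc = fecundity_config(), R = NULL) {
  p <- as_params(params)
  if (is.null(R)) {
    R <- p$recruitment_rate
    if (is.null(R)) rlang::abort("recruitment_rate missing and R not given")
  }
  P <- survival_growth_kernel(p, grid)
  F_ <- fecundity_kernel(R, fc, grid)
  assemble_kernel(P, F_, grid, fc)
}

assemble_kernel <- function(P, F_, grid = NULL, fc = NULL) {
  if (!all(dim(P) == dim(F_))) rlang::abort("P and F must be conformable")
  K <- P + F_
  eig <- dominant_eigen(K)
  structure(
    list(P = P, F = F_, K = K, grid = grid, fecundity = fc,
         lambda = eig$lambda, w = eig$w, v = eig$v),
    class = "fir_kernel"
  )
}

# dominant eigenvalue with right/left eigenvectors, via dense
# eigendecomposition; ties broken by modulus then real part
dominant_eigen <- function(K) {
  er <- eigen(K)
  i <- order(-Mod(er$values), -Re(er$values))[1]
  lambda <- Re(er$values[i])
  w <- Re(er$vectors[, i])
  w <- w / sum(w)
  el <- eigen(t(K))
  j <- order(-Mod(el$values), -Re(el$values))[1]
  v <- Re(el$vectors[, j])
  v <- v / sum(v)
  list(lambda = lambda, w = w, v = v)
}

#' Dominant eigenvalue of a nonnegative kernel matrix
#'
#' @param K A nonnegative square matrix or a `fir_kernel`.
#' @return The real dominant eigenvalue.
#' @export
dominant_lambda <- function(K) {
  if (inherits(K, "fir_kernel")) return(K$lambda)
  if (!is.matrix(K) || nrow(K) != ncol(K)) rlang::abort("K must be square")
  dominant_eigen(K)$lambda
}

#' Power iteration for the dominant eigenvalue
#'
#' Independent iterative route to the dominant eigenvalue/eigenvector, used to
#' cross-check the dense eigendecomposition.
#'
#' @param K Nonnegative square matrix.
#' @param tol Relative residual tolerance `max|Kw - lambda w| / lambda`
#'   (default 1e-10).
#' @param max_iter Iteration cap (default 1e5).
#' @return List with `lambda`, `w` (sum-one eigenvector), `iterations`,
#'   `converged`.
#' @export
power_iteration <- function(K, tol = 1e-10, max_iter = 1e5) {
  n <- nrow(K)
  w <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    Kw <- drop(K %*% w)
    lambda <- sum(w * Kw) / sum(w * w)  # Rayleigh quotient
    if (max(abs(Kw - lambda * w)) <= tol * abs(lambda)) {
      return(list(lambda = lambda, w = w / sum(w), iterations = it,
                  converged = TRUE))
    }
    w <- Kw / sum(Kw)
  }
  rlang::warn("power iteration did not converge")
  list(lambda = lambda, w = w / sum(w), iterations = max_iter, converged = FALSE)
}

#' Posterior ensemble of kernels and population growth rates
#'
#' For each joint posterior draw of the vital-rate parameters, assembles the
#' full kernel and records its dominant eigenvalue. Reports the draws, their
#' mean and SD, the elementwise mean kernel (the representative kernel used
#' for projection), and the mean kernel's own dominant eigenvalue.
#'
#' @param surv A survival `fir_posterior` (from [fit_survival()]).
#' @param growth A growth `fir_posterior` (from [fit_growth()]).
#' @param R A `fir_recruitment`, a numeric vector of rate draws, or a single
#'   fixed rate.
#' @param grid A [size_grid()].
#' @param fc A [fecundity_config()].
#' @param n_draws Ensemble size (default 1000).
#' @param seed Optional seed for drawing from the posteriors.
#' @return A `fir_lambda_ensemble` list with `lambda` (draws), `mean`, `sd`,
#'   `lambda_mean_kernel`, `mean_kernel`, and the parameter draws used.
#' @export
lambda_ensemble <- function(surv, growth, R, grid, fc = fecundity_config(),
                            n_draws = 1000, seed = NULL) {
  sd_draws <- dplyr::select(surv$draws, "surv_intercept", "surv_slope")
  gr_draws <- dplyr::select(growth$draws, "growth_intercept", "growth_slope", "growth_sd")
  if (nrow(sd_draws) < n_draws || nrow(gr_draws) < n_draws) {
    rlang::abort("posterior draw counts must be >= n_draws")
  }
  run <- function() {
    i_s <- sample.int(nrow(sd_draws), n_draws)
    i_g <- sample.int(nrow(gr_draws), n_draws)
    r <- if (inherits(R, "fir_recruitment")) {
      recruitment_draws(R, n_draws)
    } else if (length(R) == 1) {
      rep(R, n_draws)
    } else {
      R[sample.int(length(R), n_draws)]
    }
    pars <- dplyr::bind_cols(sd_draws[i_s, ], gr_draws[i_g, ],
                             tibble::tibble(recruitment_rate = r))
    lam <- numeric(n_draws)
    K_sum <- matrix(0, grid$n, grid$n)
    for (d in seq_len(n_draws)) {
      P <- survival_growth_kernel(pars[d, ], grid)
      F_ <- fecundity_kernel(pars$recruitment_rate[d], fc, grid)
      K <- P + F_
      lam[d] <- dominant_eigen(K)$lambda
      K_sum <- K_sum + K
    }
    mean_K <- K_sum / n_draws
    structure(
      list(lambda = lam, mean = mean(lam), sd = stats::sd(lam),
           lambda_mean_kernel = dominant_eigen(mean_K)$lambda,
           mean_kernel = mean_K, params = pars, grid = grid, fecundity = fc),
      class = "fir_lambda_ensemble"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.fir_kernel <- function(x, ...) {
  cat(sprintf("IPM kernel (%d x %d): lambda = %.4f per interval (annualised %.4f)\n",
              nrow(x$K), ncol(x$K), x$lambda, sqrt(max(x$lambda, 0))))
  invisible(x)
}

#' @export
print.fir_lambda_ensemble <- function(x, ...) {
  cat(sprintf("Lambda ensemble (%d draws): mean %.4f (SD %.4f); mean-kernel lambda %.4f\n",
              length(x$lambda), x$mean, x$sd, x$lambda_mean_kernel))
  invisible(x)
}

#' @describeIn lambda_ensemble Draw-level tidy view of the ensemble.
#' @param x A `fir_lambda_ensemble`.
#' @param ... Unused.
#' @method tidy fir_lambda_ensemble
#' @export
tidy.fir_lambda_ensemble <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(draw = seq_along(x$lambda), lambda = x$lambda),
                   x$params)
}

#' @describeIn lambda_ensemble One-row ensemble summary.
#' @method glance fir_lambda_ensemble
#' @export
glance.fir_lambda_ensemble <- function(x, ...) {
  tibble::tibble(
    n_draws = length(x$lambda), mean_lambda = x$mean, sd_lambda = x$sd,
    lambda_mean_kernel = x$lambda_mean_kernel,
    mean_log_lambda = mean(log(x$lambda)), sd_log_lambda = stats::sd(log(x$lambda))
  )
}
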