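#' MCMC sampler settings
#'
#' @param chains Number of chains (default 4).
#' @param warmup Warm-up (adaptation) iterations per chain, discarded.
#' @param iter Kept iterations per chain after warm-up.
#' @param seed Optional integer seed controlling all chains.
#' @return A list of class `fir_mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 4, warmup = 1000, iter = 1000, seed = NULL) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1)
  structure(list(chains = chains, warmup = warmup, iter = iter, seed = seed),
            class = "fir_mcmc_settings")
}

# Metropolis-Hastings sampler built around a mode-curvature approximation:
# proposals mix an independence step from a multivariate t centred at the
# posterior mode (near-iid draws when the posterior is close to Gaussian,
# as for these low-dimensional regressions) with random-walk steps whose
# scale adapts toward a 0.30 acceptance rate during warm-up (correctness
# guard when the posterior is far from the approximation).
# log_post must accept a numeric parameter vector and return a scalar.
mh_sample <- function(log_post, init, vcov, par_names,
                      settings = mcmc_settings(), p_indep = 0.8,
                      indep_inflate = 1.4, indep_df = 5) {
  d <- length(init)
  vcov <- (vcov + t(vcov)) / 2
  chol_v <- tryCatch(chol(vcov), error = function(e) {
    chol(vcov + diag(1e-8 + 1e-6 * max(abs(diag(vcov))), d))
  })
  chol_q <- indep_inflate * chol_v
  # log density of the multivariate t independence proposal
  log_q <- function(th) {
    z <- backsolve(chol_q, th - init, transpose = TRUE)
    -0.5 * (indep_df + d) * log1p(sum(z^2) / indep_df)
  }
  r_q <- function() {
    z <- stats::rnorm(d) / sqrt(stats::rchisq(1, indep_df) / indep_df)
    init + drop(z %*% chol_q)
  }
  run <- function() {
    draws <- vector("list", settings$chains)
    for (ch in seq_len(settings$chains)) {
      # overdispersed start: one t-proposal draw
      theta <- r_q()
      lp <- log_post(theta)
      if (!is.finite(lp)) { theta <- init; lp <- log_post(theta) }
      log_s <- log(2.38 / sqrt(d))
      total <- settings$warmup + settings$iter
      out <- matrix(NA_real_, settings$iter, d)
      for (t in seq_len(total)) {
        if (stats::runif(1) < p_indep) {
          prop <- r_q()
          lp_prop <- log_post(prop)
          log_ratio <- (lp_prop - lp) + (log_q(theta) - log_q(prop))
          acc <- is.finite(lp_prop) && log(stats::runif(1)) < log_ratio
          if (acc) { theta <- prop; lp <- lp_prop }
        } else {
          prop <- theta + exp(log_s) * drop(stats::rnorm(d) %*% chol_v)
          lp_prop <- log_post(prop)
          acc <- is.finite(lp_prop) && log(stats::runif(1)) < (lp_prop - lp)
          if (acc) { theta <- prop; lp <- lp_prop }
          if (t <= settings$warmup) {
            log_s <- log_s + (as.numeric(acc) - 0.30) / sqrt(t)
          }
        }
        if (t > settings$warmup) out[t - settings$warmup, ] <- theta
      }
      colnames(out) <- par_names
      draws[[ch]] <- out
    }
    draws
  }
  draws <- if (is.null(settings$seed)) run() else withr::with_seed(settings$seed, run())
  coda::mcmc.list(lapply(draws, coda::mcmc))
}

draws_tibble <- function(mcl) {
  purrr::imap_dfr(mcl, function(m, ch) {
    out <- tibble::as_tibble(as.matrix(m))
    out$.chain <- as.integer(ch)
    out$.iteration <- seq_len(nrow(m))
    out
  })
}

#' Convergence diagnostics for a set of MCMC chains
#'
#' Computes the potential scale reduction factor (R-hat) and effective sample
#' size per parameter, with a pass flag when every R-hat is at or below 1.01.
#' Degenerate chains (zero within-chain variance) yield `NA` R-hat and are
#' flagged.
#'
#' @param x A fitted posterior object (e.g. from [fit_survival()]) or a
#'   `coda::mcmc.list`.
#' @return A tibble with columns `parameter`, `rhat`, `ess`, `pass`.
#' @export
mcmc_diagnostics <- function(x) {
  mcl <- if (inherits(x, "fir_posterior")) x$chains else x
  if (!inherits(mcl, "mcmc.list")) {
    rlang::abort("x must be a fir_posterior or a coda::mcmc.list")
  }
  if (length(mcl) < 2) rlang::abort("diagnostics require >= 2 chains")
  mats <- lapply(mcl, as.matrix)
  pars <- colnames(mats[[1]])
  rhat <- vapply(seq_along(pars), function(j) {
    ch <- vapply(mats, function(m) m[, j], numeric(nrow(mats[[1]])))
    split_rhat(ch)
  }, numeric(1))
  ess <- tryCatch(as.numeric(coda::effectiveSize(mcl))[seq_along(pars)],
                  error = function(e) rep(NA_real_, length(pars)))
  tibble::tibble(
    parameter = pars, rhat = rhat, ess = ess,
    pass = !is.na(rhat) & rhat <= 1.01
  )
}

# split-chain potential scale reduction factor
split_rhat <- function(ch) {
  n <- nrow(ch)
  half <- floor(n / 2)
  sub <- cbind(ch[seq_len(half), , drop = FALSE],
               ch[seq.int(n - half + 1L, n), , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# inverse of a mode curvature (negative Hessian), regularised so that a
# degenerate direction (separation, zero residual variance) still yields a
# usable proposal covariance
curvature_vcov <- function(hessian) {
  H <- (hessian + t(hessian)) / 2
  eig <- eigen(H, symmetric = TRUE)
  floor_val <- max(eig$values, 1e-12) * 1e-10
  vals <- pmax(eig$values, floor_val)
  eig$vectors %*% diag(1 / vals, length(vals)) %*% t(eig$vectors)
}

# shortest interval containing `prob` posterior mass
hdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, floor(prob * n))
  widths <- x[seq.int(k, n)] - x[seq_len(n - k + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1L])
}
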