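#' Time-averaged kernel across census intervals
#'
#' Elementwise mean of the per-interval kernels, used as a stationary
#' approximation of the population's dynamics for multi-step projection.
#'
#' @param kernels A list of `fir_kernel` objects sharing one grid.
#' @return A `fir_kernel` whose `P`, `F`, `K` are elementwise means.
#' @export
mean_kernel <- function(kernels) {
  stopifnot(length(kernels) >= 1)
  g <- kernels[[1]]$grid
  same <- vapply(kernels, function(k) {
    identical(dim(k$K), dim(kernels[[1]]$K)) &&
      (is.null(g) || isTRUE(all.equal(k$grid$mid, g$mid)))
  }, logical(1))
  if (!all(same)) rlang::abort("kernels must share one grid")
  P <- Reduce(`+`, lapply(kernels, `[[`, "P")) / length(kernels)
  F_ <- Reduce(`+`, lapply(kernels, `[[`, "F")) / length(kernels)
  assemble_kernel(P, F_, g, kernels[[1]]$fecundity)
}

#' Bin observed diameters onto the kernel grid
#'
#' Half-open cells `[edge_i, edge_{i+1})`, right-closed at the upper bound;
#' sizes outside the grid are counted in the nearest boundary cell.
#'
#' @param sizes Numeric diameters (cm).
#' @param grid A [size_grid()].
#' @return Integer counts per grid cell.
#' @export
bin_sizes <- function(sizes, grid) {
  edges <- grid$L + (0:grid$n) * grid$h
  idx <- findInterval(sizes, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), grid$n)
  tabulate(idx, nbins = grid$n)
}

#' Project the population size structure forward
#'
#' Iterates `n[t+1] = K n[t]` for a given number of census-interval steps
#' (biennial by default: 2024 to 2030 is 3 steps, 2024 to 2040 is 8).
#'
#' @param n0 Initial counts per grid cell (length `n_mesh`), or raw diameters
#'   when `grid` is supplied.
#' @param kernel A `fir_kernel` or a square projection matrix.
#' @param n_steps Number of projection steps (>= 1).
#' @param grid Optional [size_grid()] used to bin `n0` when it is raw sizes.
#' @param start_year,interval_years Optional labelling of steps as years.
#' @return A tibble with columns `step`, `year` (if labelled), `cell`,
#'   `midpoint` (if a grid is known), `count`.
#' @export
project_population <- function(n0, kernel, n_steps, grid = NULL,
                               start_year = NULL, interval_years = 2) {
  K <- if (inherits(kernel, "fir_kernel")) kernel$K else kernel
  g <- if (inherits(kernel, "fir_kernel")) kernel$grid else grid
  if (!is.null(grid) && length(n0) != nrow(K)) n0 <- bin_sizes(n0, grid)
  if (length(n0) != nrow(K)) rlang::abort("n0 length must match the kernel dimension")
  if (any(n0 < 0)) rlang::abort("n0 must be nonnegative")
  states <- matrix(NA_real_, n_steps + 1L, length(n0))
  states[1, ] <- n0
  for (s in seq_len(n_steps)) states[s + 1L, ] <- drop(K %*% states[s, ])
  out <- tidyr::expand_grid(step = 0:n_steps, cell = seq_len(ncol(states)))
  out$count <- as.vector(t(states))
  if (!is.null(g)) out$midpoint <- g$mid[out$cell]
  if (!is.null(start_year)) out$year <- start_year + out$step * interval_years
  out
}

# posterior-mode vital-rate parameters for one interval (fast, deterministic)
map_params <- function(pairs, prior_var = 5, prior_sigma_scale = 5) {
  x <- pairs$x
  y <- as.integer(pairs$survived)
  lp_s <- function(th) {
    eta <- th[1] + th[2] * x
    sum(ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE))) +
      sum(stats::dnorm(th, 0, sqrt(prior_var), log = TRUE))
  }
  s_opt <- stats::optim(c(0, 0), function(th) -lp_s(th), method = "BFGS")
  gx <- pairs$x[pairs$survived]
  gy <- pairs$x_new[pairs$survived]
  lm_fit <- stats::lm(gy ~ gx)
  lp_g <- function(th) {
    sig <- exp(th[3])
    sum(stats::dnorm(gy, th[1] + th[2] * gx, sig, log = TRUE)) +
      sum(stats::dnorm(th[1:2], 0, sqrt(prior_var), log = TRUE)) +
      stats::dnorm(sig, 0, prior_sigma_scale, log = TRUE) + log(2) + th[3]
  }
  g_opt <- stats::optim(c(stats::coef(lm_fit), log(max(stats::sigma(lm_fit), 1e-6))),
                        function(th) -lp_g(th), method = "BFGS")
  list(surv_intercept = s_opt$par[1], surv_slope = s_opt$par[2],
       growth_intercept = g_opt$par[1], growth_slope = g_opt$par[2],
       growth_sd = exp(g_opt$par[3]))
}

#' 10-fold cross-validation of the IPM forecast against a no-change null
#'
#' Individuals (tree ids) are partitioned into `k` folds. For each fold and
#' census interval, the vital-rate models are fitted (posterior mode) on the
#' other folds, the fitted kernel projects the held-out trees' start-census
#' size distribution one step, and the projection is compared to the held-out
#' trees' observed end-census distribution (survivors at their new sizes plus
#' recruits assigned to the fold). The null model predicts no change from the
#' start-census distribution. Errors are root-mean-square differences over
#' grid-cell counts (or coarse diameter classes).
#'
#' @param census A census tibble.
#' @param k Number of folds (default 10).
#' @param grid A [size_grid()]; default is built from the observed sizes.
#' @param fc A [fecundity_config()].
#' @param intervals Intervals to validate (default: all with data).
#' @param binning `"grid"` (default) for kernel cells or `"coarse"` for 5 cm
#'   diameter classes.
#' @param seed Seed for the fold assignment.
#' @return A `fir_validation` list: per-fold tibble `folds`, summary means
#'   `rmse_ipm`, `rmse_null`, and the fold assignment.
#' @export
cross_validate_ipm <- function(census, k = 10, grid = NULL,
                               fc = fecundity_config(),
                               intervals = NULL,
                               binning = c("grid", "coarse"), seed = NULL) {
  binning <- match.arg(binning)
  ids <- sort(unique(census$tree_id))
  if (k > length(ids)) rlang::abort("k exceeds the number of individuals")
  if (is.null(grid)) {
    alive_sizes <- census$dbh_cm[census$alive]
    grid <- size_grid(min(alive_sizes), max(alive_sizes))
  }
  if (is.null(intervals)) intervals <- seq_len(max(census$census_index))
  assign_folds <- function() {
    fold <- rep(seq_len(k), length.out = length(ids))
    sample(fold)
  }
  fold_of <- if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
  names(fold_of) <- as.character(ids)
  bin_fun <- function(sizes) {
    if (binning == "grid") return(bin_sizes(sizes, grid))
    edges <- seq(floor(grid$L), ceiling(grid$U) + 5, by = 5)
    idx <- pmin(pmax(findInterval(sizes, edges, rightmost.closed = TRUE), 1L),
                length(edges) - 1L)
    tabulate(idx, nbins = length(edges) - 1L)
  }
  rows <- list()
  for (ki in seq_len(k)) {
    held <- ids[fold_of == ki]
    for (iv in intervals) {
      pairs <- interval_pairs(census, iv)
      train <- dplyr::filter(pairs, !(.data$tree_id %in% held))
      test <- dplyr::filter(pairs, .data$tree_id %in% held)
      if (nrow(test) == 0 || nrow(train) < 20 || sum(train$survived) < 20) next
      pars <- map_params(train)
      n_parents_train <- nrow(train)
      rec_ids <- census$tree_id[census$census_index == iv & census$is_recruit]
      n_rec_train <- sum(!(rec_ids %in% held))
      R_train <- n_rec_train / n_parents_train
      kern <- ipm_kernel(pars, grid, fc, R = R_train)
      cur <- test$x
      nxt <- c(test$x_new[test$survived],
               census$dbh_cm[census$census_index == iv & census$is_recruit &
                               census$tree_id %in% held])
      pred_ipm <- if (binning == "grid") {
        drop(kern$K %*% bin_sizes(cur, grid))
      } else {
        # project on the kernel grid, then aggregate to coarse classes
        proj <- drop(kern$K %*% bin_sizes(cur, grid))
        edges <- seq(floor(grid$L), ceiling(grid$U) + 5, by = 5)
        idx <- pmin(pmax(findInterval(grid$mid, edges, rightmost.closed = TRUE), 1L),
                    length(edges) - 1L)
        as.vector(tapply(proj, factor(idx, levels = seq_len(length(edges) - 1L)), sum,
                         default = 0))
      }
      obs <- bin_fun(nxt)
      null_pred <- bin_fun(cur)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        fold = ki, interval = iv,
        rmse_ipm = sqrt(mean((pred_ipm - obs)^2)),
        rmse_null = sqrt(mean((null_pred - obs)^2)),
        n_test = nrow(test)
      )
    }
  }
  folds <- dplyr::bind_rows(rows)
  per_fold <- dplyr::summarise(dplyr::group_by(folds, .data$fold),
                               rmse_ipm = mean(.data$rmse_ipm),
                               rmse_null = mean(.data$rmse_null),
                               .groups = "drop")
  structure(
    list(folds = folds, per_fold = per_fold,
         rmse_ipm = mean(per_fold$rmse_ipm),
         rmse_null = mean(per_fold$rmse_null),
         fold_assignment = tibble::tibble(tree_id = ids, fold = fold_of),
         k = k, binning = binning, seed = seed),
    class = "fir_validation"
  )
}

#' @export
print.fir_validation <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s bins): RMSE IPM %.3f vs null %.3f\n",
              x$k, x$binning, x$rmse_ipm, x$rmse_null))
  invisible(x)
}

#' @describeIn cross_validate_ipm Per-fold tidy view.
#' @param x A `fir_validation`.
#' @param ... Unused.
#' @method tidy fir_validation
#' @export
tidy.fir_validation <- function(x, ...) x$per_fold

#' @describeIn cross_validate_ipm One-row summary.
#' @method glance fir_validation
#' @export
glance.fir_validation <- function(x, ...) {
  tibble::tibble(k = x$k, rmse_ipm = x$rmse_ipm, rmse_null = x$rmse_null,
                 skill = 1 - x$rmse_ipm / x$rmse_null, binning = x$binning)
}
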