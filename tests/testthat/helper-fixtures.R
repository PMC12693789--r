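# Shared fixtures, built lazily and cached for the session so heavy MCMC
# fits are computed once across test files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# reference grid used by the printed-parameter worked examples
ref_grid <- function() size_grid(3, 40, 100)

short_mcmc <- function(seed = 1) {
  mcmc_settings(chains = 4, warmup = 300, iter = 300, seed = seed)
}

# a moderately large census simulated from the published parameter table
big_census <- function() {
  fixture("big_census", function() {
    simulate_census(vital_rate_truths(), n0 = 2000, seed = 2024)
  })
}

# survival/growth/recruitment fits for the 2018-2020 interval of big_census:
# posterior widths representative of fits to a real plot of this size
table1_fits <- function() {
  fixture("table1_fits", function() {
    census <- big_census()
    st <- mcmc_settings(chains = 4, warmup = 400, iter = 400, seed = 7)
    suppressWarnings(list(
      survival = fit_survival(census, 2, st),
      growth = fit_growth(census, 2, st),
      recruitment = estimate_recruitment(census, 2)
    ))
  })
}

# single-interval truth table, convenient for targeted simulations
one_interval_truth <- function(row = 2) {
  tr <- vital_rate_truths()[row, ]
  tr$interval <- "only"
  tr
}
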