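# Small builders shared across test files.

# Balanced single-cohort records from an arbitrary mean function, built
# directly (not via simulate_trajectories) so generator and fitter can be
# cross-checked independently.
make_records <- function(mean_fun, animals = 10, weeks = seq(0, 28, 4),
                         b0_sd = 0, resid_sd = 0, variable = "bw_g",
                         seed = 1) {
  set.seed(seed)
  ids <- sprintf("x%03d", seq_len(animals))
  b0 <- rnorm(animals, 0, b0_sd)
  do.call(rbind, lapply(seq_len(animals), function(i) {
    tibble::tibble(
      animal_id = ids[i], cohort_weeks = max(weeks), week = weeks,
      variable = variable,
      value = mean_fun(weeks) + b0[i] + rnorm(length(weeks), 0, resid_sd),
      dropout = FALSE)
  }))
}

poly_fun <- function(beta) function(t) {
  out <- numeric(length(t))
  for (k in seq_along(beta)) out <- out + beta[k] * t^(k - 1)
  out
}
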