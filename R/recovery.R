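#' Parameter-recovery experiments
#'
#' The study's animal-level data are not public, so the pipeline is
#' validated the other way around: simulate cohorts whose ground truth is
#' set to a reported quantity, run the estimator, and check that it hands
#' the truth back under realistic heterogeneity, sampling schedules and
#' noise. These experiments are first-class package functionality; the
#' test suite and the acceptance script both call them.
#'
#' @name recovery-experiments
NULL

#' Recover a VLDL-TG secretion rate from a noiseless poloxamer test
#'
#' Generates a noiseless post-poloxamer TG curve with the given true
#' secretion rate and runs the slope-times-plasma-volume estimator; with
#' zero noise the estimator is exact.
#'
#' @param true_rate True secretion rate, umol TG/kg/h.
#' @param body_weight_g Body weight at test, g.
#' @param baseline_tg Baseline TG, mM.
#' @return Estimated rate, umol TG/kg/h.
#' @export
vldl_recovery <- function(true_rate, body_weight_g = 40, baseline_tg = 1.0) {
  test <- simulate_poloxamer_curve(true_rate, body_weight_g = body_weight_g,
                                   baseline_tg = baseline_tg, noise_sd = 0)
  vldl_tg_production(test)$rate_umol_kg_h
}

#' Recover a trajectory peak week from simulated cubic cohorts
#'
#' Simulates `reps` cohorts of `n_animals` sampled every 4 weeks over
#' 0-28 weeks from a cubic fixed curve whose interior extremum sits at
#' `peak_week`, with per-animal random intercepts (SD 20% of the fixed
#' curve's range), random slopes (end-of-study contribution 5% of range)
#' and residual noise (SD 10% of range); fits the degree-3 mixed model
#' and locates the extremum. Returns the mean estimated week.
#'
#' @param peak_week True week of the interior extremum.
#' @param other_stationary Week of the cubic's second stationary point
#'   (shapes the curve; may lie outside the observed range).
#' @param kind `"maximum"` or `"minimum"`.
#' @param transform Fit/simulation scale (`"sqrt"` for TG-like data).
#' @param baseline,height Fixed-curve baseline and extremum displacement
#'   on the analysis scale.
#' @param n_animals Animals per replicate.
#' @param reps Number of seeded replicates.
#' @param seed RNG seed.
#' @return List with `mean_week`, `weeks` (per replicate), `truth`.
#' @export
peak_recovery <- function(peak_week, other_stationary = 2,
                          kind = c("maximum", "minimum"),
                          transform = c("identity", "sqrt"),
                          baseline = NULL, height = NULL,
                          n_animals = 100, reps = 20, seed = 1) {
  kind <- match.arg(kind)
  transform <- match.arg(transform)
  if (is.null(baseline)) baseline <- if (transform == "sqrt") 1 else 8
  if (is.null(height)) {
    h0 <- if (transform == "sqrt") 0.8 else 0.4 * baseline
    height <- if (kind == "maximum") h0 else -h0
  }
  set.seed(seed)
  beta <- cubic_peak_coeffs(peak_week, other_stationary, baseline, height)
  wks <- seq(0, 28, 4)
  S <- diff(range(eval_poly(beta, wks)))
  truth <- trajectory_truth(beta,
                            random_sd = c(0.20 * S, 0.05 * S / 28),
                            resid_sd = 0.10 * S, transform = transform)
  weeks <- vapply(seq_len(reps), function(r) {
    de <- cohort_design(sizes = n_animals, termination_weeks = 28,
                        sampling_interval = 4, dropout_rate = 0)
    sim <- simulate_trajectories(de, truth, "tg_mM")
    fit <- fit_polynomial_lmm(sim$records, "tg_mM", 3,
                              transform = transform)
    locate_extremum(fit, kind)$week
  }, numeric(1))
  list(mean_week = mean(weeks), weeks = weeks, truth = truth)
}

#' Recover a trajectory trough week from a small quadratic cohort
#'
#' Mirrors the endogenous-glucose-production arm of the study: a single
#' cohort of `n_animals` (16 by default) measured at weeks 3/9/15/27,
#' simulated from a quadratic fixed curve with its vertex (minimum) at
#' `vertex_week`, per-animal random intercepts and residual noise both at
#' 10% of the fixed curve's range. Fits the degree-2 mixed model with
#' random intercepts and locates the minimum; returns the mean over
#' replicates.
#'
#' @param vertex_week True week of the minimum.
#' @param vertex_value Fixed-curve value at the vertex.
#' @param curvature Quadratic coefficient (> 0 for a minimum).
#' @param weeks Sampling weeks.
#' @param n_animals Animals per replicate.
#' @param reps Number of seeded replicates.
#' @param seed RNG seed.
#' @return List with `mean_week`, `weeks`, `truth`.
#' @export
trough_recovery <- function(vertex_week, vertex_value = 60,
                            curvature = 0.35, weeks = c(3, 9, 15, 27),
                            n_animals = 16, reps = 50, seed = 1) {
  set.seed(seed)
  beta <- quadratic_vertex_coeffs(vertex_week, vertex_value, curvature)
  S <- diff(range(eval_poly(beta, weeks)))
  truth <- trajectory_truth(beta, random_sd = c(0.10 * S, 0),
                            resid_sd = 0.10 * S)
  est <- vapply(seq_len(reps), function(r) {
    de <- cohort_design(sizes = n_animals,
                        termination_weeks = max(weeks),
                        sampling_weeks = weeks, dropout_rate = 0)
    sim <- simulate_trajectories(de, truth, "egp_umol_kg_min")
    fit <- fit_polynomial_lmm(sim$records, "egp_umol_kg_min", 2,
                              random = "intercept")
    locate_extremum(fit, "minimum")$week
  }, numeric(1))
  list(mean_week = mean(est), weeks = est, truth = truth)
}

#' Recover marginal and conditional R-squared from simulated growth data
#'
#' Chooses variance components in the exact proportions implied by the
#' target marginal and conditional R-squared (fixed : random : residual =
#' `marginal : conditional - marginal : 1 - conditional`), simulates
#' body-weight-like cohorts from a quadratic fixed curve with random
#' intercepts, fits the degree-2 mixed model, and applies the variance
#' decomposition. Returns the mean recovered pair over replicates.
#'
#' @param marginal,conditional Target R-squared values.
#' @param n_animals Animals per replicate.
#' @param reps Number of seeded replicates.
#' @param seed RNG seed.
#' @return List with `marginal_r2`, `conditional_r2` (means), per-rep
#'   values, and the generating variance components.
#' @export
r2_recovery <- function(marginal = 0.47, conditional = 0.98,
                        n_animals = 100, reps = 20, seed = 1) {
  stopifnot(marginal > 0, conditional >= marginal, conditional < 1)
  set.seed(seed)
  # body-weight-like quadratic: plateauing growth, maximum at week 18
  beta <- quadratic_vertex_coeffs(18, 50, -20 / 324)
  wks <- seq(0, 28, 4)
  fx <- eval_poly(beta, wks)
  var_fixed <- mean((fx - mean(fx))^2)
  var_random <- var_fixed * (conditional - marginal) / marginal
  var_resid <- var_fixed * (1 - conditional) / marginal
  truth <- trajectory_truth(beta, random_sd = c(sqrt(var_random), 0),
                            resid_sd = sqrt(var_resid))
  out <- vapply(seq_len(reps), function(r) {
    de <- cohort_design(sizes = n_animals, termination_weeks = 28,
                        sampling_interval = 4, dropout_rate = 0)
    sim <- simulate_trajectories(de, truth, "bw_g")
    fit <- fit_polynomial_lmm(sim$records, "bw_g", 2, random = "intercept")
    fit$r2
  }, numeric(2))
  list(marginal_r2 = mean(out[1, ]), conditional_r2 = mean(out[2, ]),
       per_rep = out,
       components = c(var_fixed = var_fixed, var_random = var_random,
                      var_resid = var_resid))
}
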