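test_that("constant data give the constant as intercept with ~zero variances", {
  rec <- make_records(function(t) rep(10, length(t)), animals = 6,
                      weeks = seq(0, 12, 4), resid_sd = 1e-8)
  fit <- fit_polynomial_lmm(rec, "bw_g", 1, random = "intercept")
  expect_equal(fit$fixed_coeffs[1], 10, tolerance = 1e-6)
  expect_equal(fit$fixed_coeffs[2], 0, tolerance = 1e-6)
  expect_lt(fit$var_intercept, 1e-10)
})

test_that("fixed effects of known cubic truth are recovered within 3 SE", {
  beta <- c(1, 27, 0, -1) / 10
  sim <- simulate_trajectories(
    cohort_design(sizes = 100, termination_weeks = 5, sampling_interval = 1,
                  dropout_rate = 0, seed = 77),
    trajectory_truth(beta, random_sd = c(0.5, 0.05), resid_sd = 0.5))
  fit <- fit_polynomial_lmm(sim$records, "tg_mM", 3)
  expect_true(all(abs(fit$fixed_coeffs - beta) < 3 * fit$fixed_se))
})

test_that("on balanced data LMM fixed effects match the OLS polynomial fit", {
  rec <- make_records(poly_fun(c(5, 2, -0.05)), animals = 12,
                      weeks = seq(0, 28, 4), b0_sd = 1.5, resid_sd = 0.8,
                      seed = 9)
  fit <- fit_polynomial_lmm(rec, "bw_g", 2, random = "intercept")
  ols <- unname(coef(lm(value ~ week + I(week^2), data = rec)))
  expect_equal(fit$fixed_coeffs, ols, tolerance = 1e-5)
})

test_that("sqrt transform removes the fitted-value trend in |residuals|", {
  beta <- c(1.2, 0.08, -0.002, 0)
  sim <- simulate_trajectories(
    cohort_design(sizes = 80, termination_weeks = 28, dropout_rate = 0,
                  seed = 15),
    trajectory_truth(beta, random_sd = c(0.15, 0), resid_sd = 0.12,
                     transform = "sqrt"))
  fit_sqrt <- fit_polynomial_lmm(sim$records, "tg_mM", 2,
                                 transform = "sqrt", random = "intercept")
  fit_id <- fit_polynomial_lmm(sim$records, "tg_mM", 2,
                               random = "intercept")
  # heteroscedastic on the raw scale, cured on the sqrt scale
  expect_lt(fit_id$resid_abs_trend_p, 0.05)
  expect_gt(fit_sqrt$resid_abs_trend_p, 0.05)
})

test_that("degree selection escalates for curved truth and never at alpha 0", {
  cub <- simulate_trajectories(
    cohort_design(sizes = 60, termination_weeks = 28, dropout_rate = 0,
                  seed = 31),
    trajectory_truth(cubic_peak_coeffs(18, 2, 8, 4),
                     random_sd = c(0.5, 0), resid_sd = 0.5))
  sel <- select_model(cub$records, "tg_mM", random = "intercept")
  expect_equal(sel$degree, 3)
  sel0 <- select_model(cub$records, "tg_mM", alpha = 0,
                       random = "intercept")
  expect_equal(sel0$degree, 1)
})

test_that("degree selection keeps the linear model under linear truth", {
  set.seed(61)
  picks <- replicate(30, {
    rec <- make_records(poly_fun(c(5, 0.5)), animals = 25,
                        weeks = seq(0, 28, 4), b0_sd = 1, resid_sd = 1,
                        seed = sample.int(1e6, 1))
    select_model(rec, "bw_g", random = "intercept")$degree
  })
  expect_gte(mean(picks == 1), 0.8)
})

test_that("variance decomposition applies the printed formulas", {
  r2 <- biphasica:::r2_from_variances(1, 1, 2)
  expect_equal(unname(r2), c(0.25, 0.50))
  expect_error(biphasica:::r2_from_variances(0, 0, 0), "undefined")
  # no random variance forces marginal == conditional
  rec <- make_records(poly_fun(c(5, 1)), animals = 8, weeks = seq(0, 16, 4),
                      b0_sd = 0, resid_sd = 0.5, seed = 2)
  fit <- fit_polynomial_lmm(rec, "bw_g", 1, random = "intercept")
  if (fit$var_intercept < 1e-8) {
    expect_equal(fit$r2[["marginal_r2"]], fit$r2[["conditional_r2"]],
                 tolerance = 1e-6)
  }
  expect_lte(fit$r2[["marginal_r2"]], fit$r2[["conditional_r2"]])
})

test_that("marginal R2 never exceeds conditional R2 and both lie in [0,1]", {
  set.seed(8)
  for (rep in 1:5) {
    tr <- trajectory_truth(c(10, runif(1, -1, 1), runif(1, -0.05, 0.05), 0),
                           random_sd = runif(2, 0, c(3, 0.1)),
                           resid_sd = runif(1, 0.5, 2))
    sim <- simulate_trajectories(
      cohort_design(sizes = 30, termination_weeks = 28, dropout_rate = 0),
      tr, "bw_g")
    r2 <- fit_polynomial_lmm(sim$records, "bw_g", 2)$r2
    expect_lte(r2[["marginal_r2"]], r2[["conditional_r2"]] + 1e-12)
    expect_gte(r2[["marginal_r2"]], 0)
    expect_lte(r2[["conditional_r2"]], 1)
  }
})

test_that("extrema of fixed polynomials are located analytically", {
  pk <- locate_extremum(c(0, 3.6, -0.1), "maximum", c(0, 28))
  expect_equal(pk$week, 18)
  expect_true(pk$in_range)
  pk3 <- locate_extremum(c(1, 27, 0, -1), "maximum", c(0, 5))
  expect_equal(pk3$week, 3)
  expect_error(locate_extremum(c(0, 1, 0), "maximum"), "degenerate")
  expect_error(locate_extremum(c(0, 1)), "degree")
  # out-of-range minimum is reported but flagged, mirroring a fitted
  # trough before the start of the experiment
  tr <- locate_extremum(quadratic_vertex_coeffs(-4, 10, 0.1), "minimum",
                        c(0, 28))
  expect_equal(tr$week, -4)
  expect_false(tr$in_range)
})

test_that("extremum location is equivariant under week shifts", {
  set.seed(12)
  for (rep in 1:10) {
    beta <- cubic_peak_coeffs(runif(1, 5, 20), runif(1, -5, 3), 5,
                              runif(1, 0.5, 3))
    delta <- runif(1, -5, 5)
    # coefficients of f(t - delta), i.e. the curve shifted right by delta
    shifted <- sapply(0:3, function(k)
      sum(sapply(k:3, function(j)
        beta[j + 1] * choose(j, k) * (-delta)^(j - k))))
    w1 <- locate_extremum(beta, "maximum")$week
    w2 <- locate_extremum(shifted, "maximum")$week
    expect_equal(w2, w1 + delta, tolerance = 1e-8)
  }
})

test_that("BLUPs shrink toward zero and more so for sparse animals", {
  beta <- c(20, 1, -0.02)
  rec <- make_records(poly_fun(beta), animals = 30, weeks = seq(0, 28, 4),
                      b0_sd = 3, resid_sd = 2, seed = 44)
  # animal x001 observed only twice
  rec <- rec[!(rec$animal_id == "x001" & rec$week > 4), ]
  fit <- fit_polynomial_lmm(rec, "bw_g", 2, random = "intercept")
  curves <- individual_curves(fit)
  blups <- attr(curves, "blups")
  expect_equal(nrow(blups), 30)
  # mean BLUP intercept is ~0 (|mean| < 3 SE)
  expect_lt(abs(mean(blups$b0)), 3 * sd(blups$b0) / sqrt(nrow(blups)))
  # shrinkage ratio (BLUP / raw deviation) smaller for the sparse animal
  raw_dev <- function(id) {
    d <- rec[rec$animal_id == id, ]
    mean(d$value - poly_fun(fit$fixed_coeffs)(d$week))
  }
  ratio <- function(id) blups$b0[blups$animal_id == id] / raw_dev(id)
  dense_ids <- paste0("x0", sprintf("%02d", 2:11))
  expect_lt(ratio("x001"), mean(sapply(dense_ids, ratio)))
})

test_that("zero random variance collapses individual curves onto the
           population curve", {
  rec <- make_records(poly_fun(c(5, 1)), animals = 6, weeks = seq(0, 16, 4),
                      b0_sd = 0, resid_sd = 0.3, seed = 6)
  fit <- fit_polynomial_lmm(rec, "bw_g", 1, random = "intercept")
  curves <- individual_curves(fit)
  pop <- curves[curves$animal_id == ".population", ]
  for (id in unique(rec$animal_id)) {
    expect_equal(curves$value[curves$animal_id == id], pop$value,
                 tolerance = 1e-4)
  }
})
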