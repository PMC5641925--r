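test_that("noise-free constant truth yields constant records", {
  sim <- simulate_trajectories(
    cohort_design(sizes = 5, termination_weeks = 8, dropout_rate = 0,
                  seed = 3),
    trajectory_truth(c(10, 0, 0, 0), random_sd = c(0, 0), resid_sd = 1e-12))
  expect_true(all(abs(sim$records$value - 10) < 1e-9))
})

test_that("sampled group mean of the cubic 1 + 27t - t^3 peaks at week 3", {
  sim <- simulate_trajectories(
    cohort_design(sizes = 200, termination_weeks = 5, sampling_interval = 1,
                  dropout_rate = 0, seed = 5),
    trajectory_truth(c(1, 27, 0, -1), random_sd = c(2, 0), resid_sd = 2))
  gm <- tapply(sim$records$value, sim$records$week, mean)
  expect_equal(as.numeric(names(gm)[which.max(gm)]), 3)
})

test_that("same seed gives identical cohorts; dropout count matches design", {
  de <- cohort_design(seed = 42)   # default staggered 20/19/20/30 design
  tr <- trajectory_truth(c(30, 1, -0.02, 0), random_sd = c(3, 0.05),
                         resid_sd = 1)
  s1 <- simulate_trajectories(de, tr, "bw_g")
  s2 <- simulate_trajectories(de, tr, "bw_g")
  expect_identical(s1$records, s2$records)
  expect_equal(sum(s1$animals$dropout), round(10 / 115 * 89))
  # dropout animals are truncated before their cohort's termination week
  trunc <- s1$records[s1$records$dropout, ]
  last_wk <- tapply(trunc$week, trunc$animal_id, max)
  coh <- tapply(trunc$cohort_weeks, trunc$animal_id, max)
  expect_true(all(last_wk < coh))
})

test_that("sqrt-transform simulation squares the latent scale and guards
           against negative fixed curves", {
  tr <- trajectory_truth(c(2, 0.1, 0, 0), random_sd = c(0, 0),
                         resid_sd = 1e-12, transform = "sqrt")
  sim <- simulate_trajectories(
    cohort_design(sizes = 3, termination_weeks = 8, dropout_rate = 0,
                  seed = 1), tr)
  expect_equal(sim$records$value,
               (2 + 0.1 * sim$records$week)^2, tolerance = 1e-6)
  bad <- trajectory_truth(c(1, -1, 0, 0), random_sd = c(0, 0),
                          resid_sd = 0.1, transform = "sqrt")
  expect_error(
    simulate_trajectories(cohort_design(sizes = 3, termination_weeks = 8,
                                        dropout_rate = 0, seed = 1), bad),
    "nonnegative")
})

test_that("poloxamer curve slope encodes the true secretion rate", {
  flat <- simulate_poloxamer_curve(0, 40, 1.0, 0)
  expect_equal(flat$tg_mM, rep(1.0, 4))
  cv <- simulate_poloxamer_curve(162, 40, 1.0, 0)
  expect_equal(cv$truth$slope_mM_h, 162 / 41.25)
  expect_equal(cv$truth$slope_mM_h, 3.927, tolerance = 1e-4)
  expect_error(simulate_poloxamer_curve(100, noise_sd = -0.1), "nonnegative")
})

test_that("VLDL estimator is unbiased over noisy simulated tests", {
  set.seed(21)
  est <- replicate(50, {
    vldl_tg_production(simulate_poloxamer_curve(162, 40, 1.0,
                                                noise_sd = 0.2))$rate_umol_kg_h
  })
  expect_lt(abs(mean(est) / 162 - 1), 0.02)
})

test_that("simulated MIDs are normalized with binomial excess structure", {
  m0 <- simulate_mid(8, 0.05, 0, 0)
  # unlabeled: measured equals the fragment's natural-abundance pattern
  pat <- isotope_pattern("C17H34O2")
  expect_equal(m0$measured[seq_along(pat)], pat / sum(pat),
               tolerance = 1e-9)
  m1 <- simulate_mid(8, 0.05, 1, 0)
  expect_equal(m1$excess_true[3] / m1$excess_true[2], 0.1842105,
               tolerance = 1e-6)
  expect_equal(sum(m1$excess_true), 1, tolerance = 1e-9)
  expect_equal(sum(m1$measured), 1, tolerance = 1e-9)
  expect_error(simulate_mid(8, 0.6, 0.5), "p")
  expect_error(simulate_mid(8, 0.05, 0.8, 0.3), "<= 1")
})

test_that("D2-glucose curve follows the Bateman form", {
  cv <- simulate_d2glucose_curve(2, 20, 20, k_a = 0.15, k_e = 0.02)
  expect_equal(cv$enrichment[1], 0)        # nothing absorbed at t = 0
  expect_error(simulate_d2glucose_curve(2, 20, 20, k_a = 0.02, k_e = 0.02),
               "k_a must exceed k_e")
  # near-instant absorption approaches the one-exponential bolus whose
  # AUC is dose / (Vd * k_e)
  t <- c(0, 5, 10, 20, 30, 45, 60, 75, 90)
  fast <- simulate_d2glucose_curve(2, 20, 20, k_a = 50, k_e = 0.02,
                                   times_min = t)
  tracee <- 8 * 180.16 / 1000
  tracer <- fast$enrichment / (1 - fast$enrichment) * tracee
  expect_equal(tracer[-1], (2 / 20) * exp(-0.02 * t[-1]), tolerance = 1e-3)
})
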