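test_that("noiseless Bateman curves are recovered to solver precision", {
  cv <- simulate_d2glucose_curve(2, 20, 20, k_a = 0.15, k_e = 0.02)
  fit <- fit_bateman(cv)
  expect_equal(fit$k_a, 0.15, tolerance = 1e-6)
  expect_equal(fit$k_e, 0.02, tolerance = 1e-6)
  expect_equal(fit$amplitude, cv$truth$amplitude, tolerance = 1e-6)
})

test_that("the reparameterized fit resolves the absorption/elimination
           role swap", {
  # data generated with (ka, ke) = (0.4, 0.015); every start converges to
  # the same optimum with ka > ke
  cv <- simulate_d2glucose_curve(2, 25, 22, k_a = 0.4, k_e = 0.015)
  fit <- fit_bateman(cv)
  expect_gt(fit$k_a, fit$k_e)
  expect_equal(fit$k_e, 0.015, tolerance = 1e-5)
  expect_equal(fit$k_a, 0.4, tolerance = 1e-4)
})

test_that("kinetic parameters follow the closed-form moment arithmetic", {
  # hand check: dose 2 mg, Vd 20 mL, ke 0.02/min, near-instant absorption
  # in a 20 g mouse -> AUC 5 mg min/mL, MCR 0.4 mL/min = 20 mL/kg/min
  fit <- list(amplitude = 2 / 20, k_e = 0.02, k_a = 1e9)
  cv <- list(dose_mg = 2, body_weight_g = 20, glucose_mM = 8.3259)
  tp <- turnover_parameters(fit, cv)
  expect_equal(tp$auc_mg_min_ml, 5, tolerance = 1e-6)
  expect_equal(tp$mcr_ml_kg_min, 20, tolerance = 1e-6)
  # glucose 8.3259 mM = 1.5 mg/mL -> EGP 30 mg/kg/min = 166.5 umol/kg/min
  expect_equal(tp$egp_mg_kg_min, 30, tolerance = 1e-4)
  expect_equal(tp$egp_umol_kg_min, 30 / 180.16 * 1000, tolerance = 1e-4)
  # halved bioavailability halves clearance and production
  tp5 <- turnover_parameters(fit, cv, F_bioavail = 0.5)
  expect_equal(tp5$mcr_ml_kg_min, tp$mcr_ml_kg_min / 2)
  expect_equal(tp5$egp_umol_kg_min, tp$egp_umol_kg_min / 2)
})

test_that("Vd = MCR x MRT holds for every fitted output", {
  set.seed(10)
  for (rep in 1:5) {
    cv <- simulate_d2glucose_curve(
      2, 22, runif(1, 15, 30), k_a = runif(1, 0.1, 0.5),
      k_e = runif(1, 0.01, 0.05), noise_sd = 0.003)
    tp <- turnover_parameters(fit_bateman(cv), cv)
    expect_equal(tp$vd_ml_kg, tp$mcr_ml_kg_min * tp$mrt_min,
                 tolerance = 1e-9)
  }
})

test_that("fast absorption converges to the single-exponential clearance
           within 1%", {
  t <- c(0, 2, 5, 10, 20, 30, 45, 60, 75, 90)
  cv <- simulate_d2glucose_curve(2, 20, 20, k_a = 2, k_e = 0.02,
                                 times_min = t)
  tp <- turnover_parameters(fit_bateman(cv), cv)
  # one-exponential limit: MCR = dose / (C0 / ke) with C0 = dose/Vd
  mcr_limit <- 20 * 0.02 / 0.020                 # mL/kg/min at 20 g
  expect_lt(abs(tp$mcr_ml_kg_min / mcr_limit - 1), 0.01)
})

test_that("MCR and EGP recovery stays within 10% median error under
           5% noise", {
  set.seed(30)
  rel_err <- replicate(30, {
    Vd <- runif(1, 15, 30); ka <- runif(1, 0.1, 0.4)
    ke <- runif(1, 0.015, 0.05)
    cv <- simulate_d2glucose_curve(2, 22, Vd, ka, ke, noise_sd = 0.005)
    tp <- turnover_parameters(fit_bateman(cv), cv)
    true_mcr <- Vd * ke / 0.022                  # mL/kg/min
    abs(tp$mcr_ml_kg_min / true_mcr - 1)
  })
  expect_lt(median(rel_err), 0.1)
})

test_that("insulin sensitivity indices scale reciprocally with insulin", {
  res <- list(mcr_ml_kg_min = 20, egp_umol_kg_min = 150)
  is1 <- insulin_sensitivity_indices(res, 8, 2)
  is2 <- insulin_sensitivity_indices(res, 8, 4)
  expect_equal(is2$is_overall, is1$is_overall / 2)
  expect_equal(is2$is_peripheral, is1$is_peripheral / 2)
  expect_equal(is2$is_hepatic, is1$is_hepatic / 2)
  # lower EGP at fixed insulin means higher hepatic sensitivity
  res_lo <- list(mcr_ml_kg_min = 20, egp_umol_kg_min = 100)
  expect_gt(insulin_sensitivity_indices(res_lo, 8, 2)$is_hepatic,
            is1$is_hepatic)
  expect_error(insulin_sensitivity_indices(res, 8, 0), "insulin")
})
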