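#' Fit a Bateman curve to a tracer time course
#'
#' The tracer concentration series (enrichment times total glucose,
#' mg/mL) is fit to `A * (exp(-ke t) - exp(-ka t))` by nonlinear least
#' squares. `ka > ke` is enforced by the reparameterization
#' `ka = ke + exp(delta)`, which also removes the exchange-of-roles
#' ambiguity of the two exponentials; a small multistart grid over
#' plausible rate constants guards against local minima.
#'
#' @param curve A `tracer_curve` (see [simulate_d2glucose_curve()]), or any
#'   list with `times_min`, `enrichment`, `glucose_mM`, `dose_mg`,
#'   `body_weight_g`.
#' @param glucose_mw Molar mass of glucose, g/mol.
#' @return List with `amplitude` (mg/mL), `k_a`, `k_e` (/min), the fitted
#'   tracer concentrations, residuals, and the converged `nls` object.
#' @export
fit_bateman <- function(curve, glucose_mw = 180.16) {
  t <- curve$times_min
  if (sum(t > 0) < 5) stop("need at least 5 post-dose points", call. = FALSE)
  tracee <- curve$glucose_mM * glucose_mw / 1000
  y <- curve$enrichment / (1 - curve$enrichment) * tracee   # mg/mL tracer
  model <- function(par) {
    par[1] * (exp(-par[2] * t) - exp(-(par[2] + exp(par[3])) * t))
  }
  starts <- expand.grid(ke = c(0.005, 0.02, 0.08),
                        delta = log(c(0.02, 0.1, 0.5)))
  a0 <- max(y) / 0.5
  best <- NULL; best_rss <- Inf; diag_log <- character(0)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(A = a0, ke = starts$ke[i], delta = starts$delta[i]),
        fn = function(par) model(par) - y,
        lower = c(0, 1e-6, -15), upper = c(Inf, 5, 15),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) {
        diag_log <<- c(diag_log, conditionMessage(e)); NULL
      })
    if (!is.null(fit) && fit$info %in% 1:4 && fit$deviance < best_rss) {
      best <- fit; best_rss <- fit$deviance
    }
  }
  if (is.null(best)) {
    stop("Bateman fit failed over all starts: ",
         paste(unique(diag_log), collapse = "; "), call. = FALSE)
  }
  cf <- best$par
  list(amplitude = unname(cf["A"]), k_e = unname(cf["ke"]),
       k_a = unname(cf["ke"] + exp(cf["delta"])),
       fitted = model(cf), residuals = y - model(cf),
       rss = best_rss, fit = best)
}

#' Glucose kinetic parameters from a fitted bolus curve
#'
#' Closed-form moments of the Bateman curve give `AUC = A (1/ke - 1/ka)`
#' and `AUMC = A (1/ke^2 - 1/ka^2)`, hence `MRT = AUMC/AUC`. Clearance is
#' dose over exposure, `MCR = F * dose / AUC`, the apparent distribution
#' volume is `Vd = MCR * MRT`, the pool is `Vd * [glucose]`, and at steady
#' state the isotope-dilution identity gives `EGP = MCR * [glucose]`.
#' After an intraperitoneal bolus the absolute bioavailability F is not
#' identifiable without an intravenous reference, so `F = 1` by default
#' and clearance/volume outputs are apparent quantities; MRT includes the
#' absorption phase (an IV-referenced MRT would subtract `1/ka`). The
#' tracee concentration is taken as the mean of measured glucose over the
#' test (quasi-steady assumption).
#'
#' @param fit A [fit_bateman()] result.
#' @param curve The tracer curve the fit came from.
#' @param F_bioavail Assumed bioavailability fraction.
#' @param glucose_mw Molar mass of glucose, g/mol.
#' @return A list of class `turnover_result`: `auc_mg_min_ml`, `mrt_min`,
#'   `vd_ml_kg`, `mcr_ml_kg_min`, `pool_umol_kg`, `egp_umol_kg_min`, and
#'   the assumptions used.
#' @export
turnover_parameters <- function(fit, curve, F_bioavail = 1,
                                glucose_mw = 180.16) {
  stopifnot(F_bioavail > 0, F_bioavail <= 1)
  auc <- fit$amplitude * (1 / fit$k_e - 1 / fit$k_a)
  if (auc <= 0) stop("nonpositive AUC", call. = FALSE)
  aumc <- fit$amplitude * (1 / fit$k_e^2 - 1 / fit$k_a^2)
  mrt <- aumc / auc
  bw_kg <- curve$body_weight_g / 1000
  mcr_ml_min <- F_bioavail * curve$dose_mg / auc
  mcr_ml_kg_min <- mcr_ml_min / bw_kg
  vd_ml_kg <- mcr_ml_kg_min * mrt
  gluc <- mean(curve$glucose_mM)               # quasi-steady tracee, mM
  gluc_mg_ml <- gluc * glucose_mw / 1000
  pool_mg_kg <- vd_ml_kg * gluc_mg_ml
  egp_mg_kg_min <- mcr_ml_kg_min * gluc_mg_ml
  structure(list(
    auc_mg_min_ml = auc, aumc = aumc, mrt_min = mrt,
    F_bioavail = F_bioavail,
    mcr_ml_kg_min = mcr_ml_kg_min, vd_ml_kg = vd_ml_kg,
    pool_mg_kg = pool_mg_kg,
    pool_umol_kg = pool_mg_kg / glucose_mw * 1000,
    egp_mg_kg_min = egp_mg_kg_min,
    egp_umol_kg_min = egp_mg_kg_min / glucose_mw * 1000,
    steady_glucose_mM = gluc,
    notes = c("F assumed (IP bolus, no IV reference): apparent MCR/Vd",
              "MRT includes absorption phase",
              "tracee = mean measured glucose (quasi-steady)")),
    class = "turnover_result")
}

#' Insulin sensitivity indices from turnover results
#'
#' Index definitions (common mouse-tracer practice; stamped into the
#' output so downstream tables are auditable):
#' overall `1/(glucose x insulin)`, peripheral `MCR/insulin`, hepatic
#' `1/(EGP x insulin)`.
#'
#' @param result A [turnover_parameters()] result.
#' @param steady_glucose_mM Steady glucose, mM.
#' @param insulin_ngml Post-test plasma insulin, ng/mL, > 0.
#' @return List with `is_overall`, `is_peripheral`, `is_hepatic` and the
#'   definitions used.
#' @export
insulin_sensitivity_indices <- function(result, steady_glucose_mM,
                                        insulin_ngml) {
  if (any(insulin_ngml <= 0)) stop("insulin must be positive", call. = FALSE)
  if (any(steady_glucose_mM <= 0)) stop("glucose must be positive",
                                        call. = FALSE)
  list(is_overall = 1 / (steady_glucose_mM * insulin_ngml),
       is_peripheral = result$mcr_ml_kg_min / insulin_ngml,
       is_hepatic = 1 / (result$egp_umol_kg_min * insulin_ngml),
       definitions = c(
         is_overall = "1 / (glucose_mM * insulin_ngml)",
         is_peripheral = "MCR_ml_kg_min / insulin_ngml",
         is_hepatic = "1 / (EGP_umol_kg_min * insulin_ngml)"))
}
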