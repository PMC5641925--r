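#' Ground-truth description of a longitudinal trajectory
#'
#' Fixed-effect polynomial (on the analysis scale), between-animal random
#' effect SDs and residual SD used by [simulate_trajectories()]. When
#' `transform = "sqrt"` the polynomial and all noise act on the square-root
#' scale and simulated values are squared back to the original scale,
#' mirroring the variance-stabilizing transform used when fitting
#' right-skewed concentrations such as plasma TG.
#'
#' @param fixed_coeffs Numeric vector of polynomial coefficients
#'   (intercept first), degree at most 3.
#' @param random_sd Length-2 numeric: SD of per-animal random intercept and
#'   random linear slope (per week), on the analysis scale.
#' @param resid_sd Residual SD, > 0, on the analysis scale.
#' @param transform `"identity"` or `"sqrt"`.
#' @return A list of class `trajectory_truth`.
#' @export
trajectory_truth <- function(fixed_coeffs, random_sd = c(0, 0), resid_sd,
                             transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  stopifnot(length(fixed_coeffs) >= 1, length(fixed_coeffs) <= 4,
            length(random_sd) == 2, all(random_sd >= 0), resid_sd > 0)
  structure(list(fixed_coeffs = as.numeric(fixed_coeffs),
                 random_sd = as.numeric(random_sd),
                 resid_sd = resid_sd, transform = transform),
            class = "trajectory_truth")
}

#' Staggered-cohort study design
#'
#' Default design: four cohorts of 20/19/20/30 animals terminated at
#' 4/9/13/28 weeks on diet, sampled every 4 weeks from week 0, with a
#' 10/115 dropout fraction truncated at a uniformly random week.
#'
#' @param sizes Cohort sizes.
#' @param termination_weeks Cohort termination weeks (same length as
#'   `sizes`).
#' @param sampling_interval Weeks between scheduled samplings.
#' @param sampling_weeks Optional explicit sampling schedule; overrides
#'   `sampling_interval` (each animal keeps the weeks up to its
#'   termination).
#' @param dropout_rate Fraction of animals terminated prematurely.
#' @param seed Optional integer seed applied by the simulator.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(sizes = c(20L, 19L, 20L, 30L),
                          termination_weeks = c(4, 9, 13, 28),
                          sampling_interval = 4,
                          sampling_weeks = NULL,
                          dropout_rate = 10 / 115,
                          seed = NULL) {
  stopifnot(length(sizes) == length(termination_weeks),
            all(sizes > 0), all(termination_weeks > 0),
            sampling_interval > 0, dropout_rate >= 0, dropout_rate < 1)
  if (!is.null(sampling_weeks)) {
    stopifnot(all(sampling_weeks >= 0),
              all(sampling_weeks <= max(termination_weeks)))
    sampling_weeks <- sort(unique(as.numeric(sampling_weeks)))
  }
  structure(list(sizes = as.integer(sizes),
                 termination_weeks = as.numeric(termination_weeks),
                 sampling_interval = sampling_interval,
                 sampling_weeks = sampling_weeks,
                 dropout_rate = dropout_rate,
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "cohort_design")
}

design_weeks <- function(design, termination) {
  if (!is.null(design$sampling_weeks)) {
    wk <- design$sampling_weeks[design$sampling_weeks <= termination]
  } else {
    wk <- seq(0, termination, by = design$sampling_interval)
  }
  if (!length(wk)) stop("no sampling weeks within cohort span", call. = FALSE)
  wk
}

eval_poly <- function(coeffs, t) {
  out <- numeric(length(t))
  for (k in seq_along(coeffs)) out <- out + coeffs[k] * t^(k - 1)
  out
}

#' Cubic fixed-effect coefficients with a prescribed interior extremum
#'
#' Builds a degree-3 polynomial whose derivative has roots exactly at
#' `extremum_week` and `other_stationary_week`, scaled so the value at the
#' interior extremum lies `height` above (maximum) or below (minimum) the
#' baseline `f(0)`. Used to place a simulated trajectory's peak at a known
#' week for recovery tests.
#'
#' @param extremum_week Week of the interior extremum.
#' @param other_stationary_week The second stationary point (may lie outside
#'   the observed range); must differ from `extremum_week`.
#' @param baseline Value of the curve at week 0.
#' @param height Signed displacement of the extremum relative to baseline:
#'   positive for a maximum, negative for a minimum.
#' @return Numeric coefficients `c(b0, b1, b2, b3)`.
#' @export
cubic_peak_coeffs <- function(extremum_week, other_stationary_week,
                              baseline, height) {
  r1 <- extremum_week; r2 <- other_stationary_week
  stopifnot(r1 != r2, height != 0)
  # antiderivative of 3 (t - r1)(t - r2); extremum displacement fixes scale
  h <- function(t) t^3 - 1.5 * (r1 + r2) * t^2 + 3 * r1 * r2 * t
  a <- height / h(r1)
  c(baseline, a * 3 * r1 * r2, -a * 1.5 * (r1 + r2), a)
}

#' Quadratic coefficients with a prescribed vertex
#'
#' @param vertex_week Week of the parabola's vertex.
#' @param vertex_value Value of the curve at the vertex.
#' @param curvature Second-derivative / 2 (coefficient of `t^2`); positive
#'   for a minimum, negative for a maximum.
#' @return Numeric coefficients `c(b0, b1, b2)`.
#' @export
quadratic_vertex_coeffs <- function(vertex_week, vertex_value, curvature) {
  stopifnot(curvature != 0)
  c(vertex_value + curvature * vertex_week^2,
    -2 * curvature * vertex_week, curvature)
}

#' Simulate longitudinal trajectories with known ground truth
#'
#' Generates, for each animal, `y_ij = poly(beta, t_ij) + b0_i + b1_i t_ij
#' + e_ij` on the analysis scale, back-transformed (squared) when the truth
#' uses the sqrt transform. Cohorts are staggered: an animal in the w-week
#' cohort is sampled at weeks `0, interval, ..., <= w`. A randomly chosen
#' `dropout_rate` fraction of animals is truncated at a uniform random week
#' and flagged `dropout = TRUE` (dropout independent of outcome, i.e. MCAR;
#' real attrition tied to weight loss may be informative).
#'
#' @param design A [cohort_design()].
#' @param truth A [trajectory_truth()].
#' @param variable Variable token for the generated records.
#' @return A list with `records` (a `long_records` tibble), `truth`,
#'   `design`, and `animals` (per-animal random effects).
#' @export
simulate_trajectories <- function(design, truth, variable = "tg_mM") {
  stopifnot(inherits(design, "cohort_design"),
            inherits(truth, "trajectory_truth"))
  if (!is.null(design$seed)) set.seed(design$seed)
  weeks_all <- sort(unique(unlist(lapply(design$termination_weeks,
                                         function(w) design_weeks(design, w)))))
  if (truth$transform == "sqrt" &&
      any(eval_poly(truth$fixed_coeffs, weeks_all) < 0)) {
    stop("sqrt transform requires the fixed curve to stay nonnegative ",
         "over the sampled weeks", call. = FALSE)
  }
  n_total <- sum(design$sizes)
  ids <- sprintf("m%03d", seq_len(n_total))
  cohort <- rep(design$termination_weeks, design$sizes)
  b0 <- rnorm(n_total, 0, truth$random_sd[1])
  b1 <- rnorm(n_total, 0, truth$random_sd[2])
  n_drop <- round(design$dropout_rate * n_total)
  drop_idx <- if (n_drop > 0) sample.int(n_total, n_drop) else integer(0)

  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    wk <- design_weeks(design, cohort[i])
    is_drop <- i %in% drop_idx
    if (is_drop && length(wk) > 1) {
      # truncate at a uniformly chosen week strictly before termination
      cut <- runif(1, 0, cohort[i])
      wk <- wk[wk <= cut]
      if (!length(wk)) wk <- design_weeks(design, cohort[i])[1]
    }
    y <- eval_poly(truth$fixed_coeffs, wk) + b0[i] + b1[i] * wk +
      rnorm(length(wk), 0, truth$resid_sd)
    if (truth$transform == "sqrt") y <- pmax(y, 0)^2
    rows[[i]] <- tibble::tibble(
      animal_id = ids[i], cohort_weeks = cohort[i], week = wk,
      variable = variable, value = y, dropout = is_drop)
  }
  rec <- do.call(rbind, rows)
  list(records = validate_long_records(rec),
       truth = truth, design = design,
       animals = tibble::tibble(animal_id = ids, cohort_weeks = cohort,
                                b0 = b0, b1 = b1,
                                dropout = seq_len(n_total) %in% drop_idx))
}

#' Simulate a post-poloxamer TG accumulation curve
#'
#' After lipoprotein-lipase blockade, plasma TG rises linearly; the slope
#' in mM/h equals the true secretion rate (umol TG/kg/h) divided by the
#' plasma volume per kg (41.25 mL/kg by default).
#'
#' @param true_rate True VLDL-TG secretion rate, umol TG/kg/h, >= 0.
#' @param body_weight_g Body weight at test, g.
#' @param baseline_tg Pre-injection plasma TG, mM.
#' @param noise_sd Gaussian noise SD on each TG value, mM, >= 0.
#' @param times_min Sampling times in minutes; must include 0 and at least
#'   two later points.
#' @param blood_ml_per_kg,hematocrit Plasma-volume constants.
#' @return A list of class `poloxamer_test` with `times_min`, `tg_mM`,
#'   `body_weight_g` and the generating `truth`.
#' @export
simulate_poloxamer_curve <- function(true_rate, body_weight_g = 40,
                                     baseline_tg = 1.0, noise_sd = 0,
                                     times_min = c(0, 30, 60, 180),
                                     blood_ml_per_kg = 75, hematocrit = 0.45) {
  stopifnot(true_rate >= 0, 0 %in% times_min, sum(times_min > 0) >= 2)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  pv_per_kg <- blood_ml_per_kg * (1 - hematocrit)   # mL plasma / kg
  slope_mM_h <- true_rate / pv_per_kg
  tg <- baseline_tg + slope_mM_h * times_min / 60 +
    rnorm(length(times_min), 0, noise_sd)
  tg <- pmax(tg, 0)
  structure(list(times_min = times_min, tg_mM = tg,
                 body_weight_g = body_weight_g, dose_mg_kg = 1000,
                 truth = list(rate = true_rate, slope_mM_h = slope_mM_h,
                              baseline_tg = baseline_tg)),
            class = "poloxamer_test")
}

#' Simulate a measured mass-isotopomer distribution
#'
#' The labeled-pool composition is a mixture: a fraction `f_new` of chains
#' built entirely from the labeled precursor (Binomial(`n_units`, `p`)
#' label counts), a fraction `f_elong` carrying a single freshly added unit
#' (Binomial(1, `p`)), and the remainder unlabeled. This tracer-incorporation
#' distribution is convolved with the natural-abundance pattern of the
#' derivatized fragment, optionally degraded with truncated Gaussian noise,
#' and renormalized to sum 1 — exactly what a GC/LC-MS measurement of the
#' fragment delivers.
#'
#' @param n_units Number of precursor condensation units (8 for C16:0 made
#'   de novo, 9 for C18:0).
#' @param p Precursor (acetyl) enrichment fraction, in [0, 0.5).
#' @param f_new Fraction of chains synthesized de novo.
#' @param f_elong Fraction elongated by one unit; `f_new + f_elong <= 1`.
#' @param fragment_formula Elemental formula of the measured fragment.
#' @param noise_sd SD of truncated Gaussian noise per channel.
#' @param skeleton_correction Passed to [build_correction_matrix()].
#' @return List with `measured` (noisy, renormalized MID), `excess_true`
#'   (the tracer-incorporation distribution), and the correction matrix
#'   used for the forward convolution.
#' @export
simulate_mid <- function(n_units, p, f_new, f_elong = 0,
                         fragment_formula = "C17H34O2", noise_sd = 0,
                         skeleton_correction = TRUE) {
  stopifnot(p >= 0, p < 0.5, f_new >= 0, f_elong >= 0)
  if (f_new + f_elong > 1) stop("f_new + f_elong must be <= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  x <- numeric(n_units + 1)
  x[1] <- 1 - f_new - f_elong
  x <- x + f_new * dbinom(0:n_units, n_units, p)
  x[1:2] <- x[1:2] + f_elong * dbinom(0:1, 1, p)
  C <- build_correction_matrix(fragment_formula, n_labels = n_units,
                               shift = 1L,
                               skeleton_correction = skeleton_correction)
  measured <- as.numeric(C %*% x)
  if (noise_sd > 0) {
    measured <- pmin(pmax(measured + rnorm(length(measured), 0, noise_sd),
                          0), 1)
  }
  measured <- measured / sum(measured)
  list(measured = measured, excess_true = x, correction_matrix = C,
       truth = list(n_units = n_units, p = p, f_new = f_new,
                    f_elong = f_elong))
}

#' Simulate a D2-glucose bolus enrichment time course
#'
#' After an intraperitoneal bolus, tracer concentration follows the Bateman
#' form `(dose/Vd) * ka/(ka - ke) * (exp(-ke t) - exp(-ka t))` —
#' first-order absorption from the peritoneum into a single well-mixed
#' glucose pool with first-order elimination. Enrichment is
#' tracer / (tracer + tracee) with the tracee pool held at the measured
#' glucose concentration.
#'
#' @param dose_mg Tracer dose, mg.
#' @param body_weight_g Body weight, g.
#' @param Vd_ml Volume of distribution, mL.
#' @param k_a Absorption rate constant, /min; must exceed `k_e`.
#' @param k_e Elimination rate constant, /min, > 0.
#' @param glucose_mM Steady tracee glucose concentration, mM.
#' @param times_min Sampling times (minutes), including 0.
#' @param noise_sd Gaussian noise SD on enrichment, >= 0.
#' @param glucose_mw Molar mass of glucose, g/mol.
#' @return A list of class `tracer_curve` with times, enrichment, glucose,
#'   dose, body weight and the generating `truth`.
#' @export
simulate_d2glucose_curve <- function(dose_mg, body_weight_g, Vd_ml,
                                     k_a, k_e, glucose_mM = 8,
                                     times_min = c(0, 10, 20, 30, 40, 50,
                                                   60, 75, 90),
                                     noise_sd = 0, glucose_mw = 180.16) {
  stopifnot(dose_mg > 0, Vd_ml > 0, k_e > 0)
  if (k_a <= k_e) {
    stop("k_a must exceed k_e (degenerate Bateman curve otherwise)",
         call. = FALSE)
  }
  tracer <- (dose_mg / Vd_ml) * k_a / (k_a - k_e) *
    (exp(-k_e * times_min) - exp(-k_a * times_min))        # mg/mL
  tracee <- glucose_mM * glucose_mw / 1000                 # mg/mL
  enr <- tracer / (tracer + tracee)
  if (noise_sd > 0) {
    enr <- pmin(pmax(enr + rnorm(length(enr), 0, noise_sd), 0), 0.999)
  }
  structure(list(times_min = times_min, enrichment = enr,
                 glucose_mM = glucose_mM, dose_mg = dose_mg,
                 body_weight_g = body_weight_g,
                 truth = list(Vd_ml = Vd_ml, k_a = k_a, k_e = k_e,
                              amplitude = (dose_mg / Vd_ml) * k_a /
                                (k_a - k_e))),
            class = "tracer_curve")
}
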