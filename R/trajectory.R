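#' Fit a polynomial linear mixed model to a longitudinal variable
#'
#' Fixed effects: polynomial in week on diet (degree 1-3, raw
#' coefficients). Random effects: per-animal intercept and linear slope
#' with unstructured covariance; if that fit is singular or fails to
#' converge, the model falls back to a random intercept only (recorded in
#' the result). Fitting is by maximum likelihood so nested fits are
#' comparable by likelihood ratio. Variables with right-skewed,
#' heteroscedastic residuals (plasma TG) can be fit on the square-root
#' scale via `transform = "sqrt"`; a monotone transform leaves extremum
#' locations unchanged.
#'
#' Internally the week axis is scaled by 1/10 to keep the cubic design
#' well-conditioned; coefficients, standard errors and variance components
#' are returned on the original weeks scale.
#'
#' @param records A `long_records` tibble (or any data frame with
#'   `animal_id`, `week`, `variable`, `value`).
#' @param variable Variable token to model.
#' @param degree Polynomial degree, 1, 2 or 3.
#' @param transform `"identity"` or `"sqrt"`.
#' @param random `"slope"` (intercept + slope, default) or `"intercept"`.
#' @param include_dropouts Keep records of prematurely terminated animals.
#' @return A list of class `mixed_fit`: `fixed_coeffs`, `fixed_se`,
#'   `vcov_fixed`, variance components (`var_intercept`, `var_slope`,
#'   `cov_int_slope`, `var_resid`), `r2` (marginal/conditional),
#'   `loglik`, `aic`, `n_animals`, `n_obs`, `degree`, `transform`,
#'   `random_structure`, `fell_back`, residual summary and the underlying
#'   `lmerMod` object.
#' @export
fit_polynomial_lmm <- function(records, variable, degree,
                               transform = c("identity", "sqrt"),
                               random = c("slope", "intercept"),
                               include_dropouts = TRUE) {
  transform <- match.arg(transform)
  random <- match.arg(random)
  stopifnot(degree %in% 1:3)
  d <- records[records$variable == variable, , drop = FALSE]
  if (!include_dropouts && "dropout" %in% names(d)) {
    d <- d[!d$dropout, , drop = FALSE]
  }
  if (nrow(d) == 0) stop("no records for variable ", variable, call. = FALSE)
  obs_per_animal <- table(d$animal_id)
  if (sum(obs_per_animal >= 2) < 3) {
    stop("need >= 2 observations for >= 3 animals", call. = FALSE)
  }
  y <- if (transform == "sqrt") {
    if (any(d$value < 0)) stop("sqrt transform on negative values",
                               call. = FALSE)
    sqrt(d$value)
  } else d$value
  s <- 10                                       # week scaling
  dat <- data.frame(y = y, w = d$week / s, animal = factor(d$animal_id))

  fit_one <- function(form) {
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = dat, REML = FALSE,
                 control = lme4::lmerControl(
                   check.conv.singular = "ignore"))))
  }
  form_slope <- stats::as.formula(
    paste0("y ~ poly(w, ", degree, ", raw = TRUE) + (1 + w | animal)"))
  form_int <- stats::as.formula(
    paste0("y ~ poly(w, ", degree, ", raw = TRUE) + (1 | animal)"))

  fell_back <- FALSE
  fit <- NULL
  if (random == "slope") {
    fit <- tryCatch(fit_one(form_slope), error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-4)) {
      fit2 <- tryCatch(fit_one(form_int), error = function(e) NULL)
      if (!is.null(fit2)) { fit <- fit2; fell_back <- TRUE }
    }
  }
  if (is.null(fit) || random == "intercept") {
    fit <- tryCatch(fit_one(form_int), error = function(e) {
      stop("mixed model failed to converge (intercept-only fallback): ",
           conditionMessage(e), call. = FALSE)
    })
    fell_back <- fell_back || random == "slope"
  }

  beta_s <- lme4::fixef(fit)
  V_s <- as.matrix(vcov(fit))
  # rescale from w = week/s back to weeks: beta_k /= s^k
  scale_vec <- s^-(0:degree)
  beta <- unname(beta_s * scale_vec)
  V <- diag(scale_vec) %*% V_s %*% diag(scale_vec)
  vc <- lme4::VarCorr(fit)$animal
  var_int <- vc[1, 1]
  has_slope <- nrow(vc) == 2
  var_slope <- if (has_slope) vc[2, 2] / s^2 else 0
  cov_is <- if (has_slope) vc[1, 2] / s else 0
  sigma2 <- stats::sigma(fit)^2

  res <- residuals(fit); fv <- fitted(fit)
  res_trend <- tryCatch(summary(lm(abs(res) ~ fv))$coefficients[2, 4],
                        error = function(e) NA_real_)

  out <- structure(list(
    fixed_coeffs = beta, fixed_se = sqrt(diag(V)), vcov_fixed = V,
    var_intercept = var_int, var_slope = var_slope,
    cov_int_slope = cov_is, var_resid = sigma2,
    degree = degree, transform = transform, variable = variable,
    random_structure = if (has_slope) "intercept+slope" else "intercept",
    fell_back = fell_back,
    weeks = d$week, week_range = range(d$week),
    n_animals = length(unique(d$animal_id)), n_obs = nrow(d),
    loglik = as.numeric(logLik(fit)), aic = AIC(fit),
    resid_abs_trend_p = res_trend,
    model = fit), class = "mixed_fit")
  out$r2 <- r2_decomposition(out)
  out
}

r2_from_variances <- function(var_fixed, var_random, var_resid) {
  tot <- var_fixed + var_random + var_resid
  if (tot <= 0) stop("all variance components are zero; R2 undefined",
                     call. = FALSE)
  c(marginal_r2 = var_fixed / tot,
    conditional_r2 = (var_fixed + var_random) / tot)
}

#' Marginal and conditional R-squared of a polynomial mixed fit
#'
#' Variance decomposition over the observed design:
#' `marginal R2 = var_fixed / (var_fixed + var_random + var_resid)` and
#' `conditional R2 = (var_fixed + var_random) / (var_fixed + var_random +
#' var_resid)`. `var_fixed` is the population variance of the fixed-effect
#' predictions at the observed weeks; `var_random` is the average over
#' observations of the random-effect variance at each design point
#' (`var_b0 + 2 cov t + var_b1 t^2`, design-dependent once slopes are
#' random); `var_resid` is the residual variance. Marginal R2 is the
#' share of variation explained by the group-mean curve alone;
#' conditional R2 adds the per-animal deviations.
#'
#' @param fit A `mixed_fit`.
#' @return Named numeric: `marginal_r2`, `conditional_r2`.
#' @export
r2_decomposition <- function(fit) {
  t <- fit$weeks
  pred_fixed <- eval_poly(fit$fixed_coeffs, t)
  var_fixed <- mean((pred_fixed - mean(pred_fixed))^2)
  var_random <- mean(fit$var_intercept + 2 * fit$cov_int_slope * t +
                       fit$var_slope * t^2)
  r2_from_variances(var_fixed, var_random, fit$var_resid)
}

#' Select polynomial degree by nested likelihood-ratio tests
#'
#' Starting from the linear model, the degree is raised while the
#' likelihood-ratio test of the added fixed term (ML fits, 1 df) is
#' significant at `alpha`. AIC for every candidate is reported alongside
#' so the selection is auditable under either criterion.
#'
#' @param records,variable,transform,random,include_dropouts As in
#'   [fit_polynomial_lmm()].
#' @param max_degree Highest degree considered (3).
#' @param alpha LRT significance level; `alpha = 0` never escalates.
#' @return The selected `mixed_fit`, with a `selection` element recording
#'   per-degree log-likelihood, AIC and LRT p-values.
#' @export
select_model <- function(records, variable, max_degree = 3,
                         transform = c("identity", "sqrt"),
                         random = c("slope", "intercept"),
                         alpha = 0.05, include_dropouts = TRUE) {
  transform <- match.arg(transform)
  random <- match.arg(random)
  fits <- lapply(1:max_degree, function(dg)
    fit_polynomial_lmm(records, variable, dg, transform = transform,
                       random = random, include_dropouts = include_dropouts))
  trace <- tibble::tibble(
    degree = 1:max_degree,
    loglik = vapply(fits, `[[`, 1.0, "loglik"),
    aic = vapply(fits, `[[`, 1.0, "aic"),
    lrt_p = NA_real_)
  chosen <- 1L
  for (dg in 2:max_degree) {
    lr <- 2 * (trace$loglik[dg] - trace$loglik[dg - 1])
    p <- stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
    trace$lrt_p[dg] <- p
    if (dg == chosen + 1L && p < alpha) chosen <- dg else break
  }
  out <- fits[[chosen]]
  out$selection <- trace
  out
}

#' Locate the fixed-effect extremum of a fitted polynomial
#'
#' Real roots of the fixed-polynomial derivative are found analytically
#' and classified by the second derivative; the requested kind of
#' extremum inside `week_range` is returned, or — when no stationary point
#' of that kind falls inside the observed range — the nearest qualifying
#' root with `in_range = FALSE` (a group-mean curve can place its
#' stationary point outside the experimental window, e.g. a fitted
#' minimum at a negative week means the curve only rises over the study).
#'
#' @param fit A `mixed_fit` of degree >= 2 (or a numeric coefficient
#'   vector).
#' @param kind `"maximum"` or `"minimum"`.
#' @param week_range Interval searched; defaults to the observed weeks.
#' @return A list of class `peak_estimate`: `week`, `kind`, `in_range`.
#' @export
locate_extremum <- function(fit, kind = c("maximum", "minimum"),
                            week_range = NULL) {
  kind <- match.arg(kind)
  beta <- if (is.numeric(fit)) fit else fit$fixed_coeffs
  if (is.null(week_range)) {
    week_range <- if (is.numeric(fit)) c(-Inf, Inf) else fit$week_range
  }
  degree <- length(beta) - 1L
  if (degree < 2) stop("degree must be >= 2 for an interior extremum",
                       call. = FALSE)
  dcoef <- beta[-1] * seq_len(degree)            # derivative coefficients
  if (all(abs(dcoef[-1]) < 1e-12)) {
    stop("degenerate polynomial: no interior extremum", call. = FALSE)
  }
  roots <- polyroot(dcoef)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  if (!length(real)) stop("no real stationary point", call. = FALSE)
  d2coef <- dcoef[-1] * seq_len(degree - 1L)
  curv <- eval_poly(d2coef, real)
  want <- if (kind == "maximum") real[curv < 0] else real[curv > 0]
  if (!length(want)) {
    stop("no stationary point of kind '", kind, "'", call. = FALSE)
  }
  inside <- want[want >= week_range[1] & want <= week_range[2]]
  if (length(inside)) {
    wk <- inside[which.min(abs(inside - mean(week_range)))]
    in_range <- TRUE
  } else {
    wk <- want[which.min(pmin(abs(want - week_range[1]),
                              abs(want - week_range[2])))]
    in_range <- FALSE
  }
  structure(list(week = wk, kind = kind, in_range = in_range),
            class = "peak_estimate")
}

#' Per-animal BLUP trajectories
#'
#' Evaluates the population (fixed-effect) polynomial and each animal's
#' BLUP-adjusted curve on a week grid. Random-effect predictions are
#' shrunken towards zero, so sparsely observed animals sit closer to the
#' population curve than their own least-squares line would.
#'
#' @param fit A `mixed_fit`.
#' @param weeks Evaluation grid; defaults to the observed weeks.
#' @return A tibble with `animal_id` (`".population"` for the fixed
#'   curve), `week`, `value` (analysis scale), plus the per-animal random
#'   effects as attribute `"blups"`.
#' @export
individual_curves <- function(fit, weeks = NULL) {
  if (is.null(weeks)) weeks <- sort(unique(fit$weeks))
  re <- lme4::ranef(fit$model)$animal
  s <- 10
  b0 <- re[, "(Intercept)"]
  b1 <- if ("w" %in% colnames(re)) re[, "w"] / s else rep(0, nrow(re))
  pop <- eval_poly(fit$fixed_coeffs, weeks)
  rows <- list(tibble::tibble(animal_id = ".population", week = weeks,
                              value = pop))
  for (i in seq_len(nrow(re))) {
    rows[[i + 1]] <- tibble::tibble(
      animal_id = rownames(re)[i], week = weeks,
      value = pop + b0[i] + b1[i] * weeks)
  }
  out <- do.call(rbind, rows)
  attr(out, "blups") <- tibble::tibble(animal_id = rownames(re),
                                       b0 = b0, b1 = b1)
  out
}
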