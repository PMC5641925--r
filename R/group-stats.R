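#' Cross-sectional comparison of cohorts
#'
#' Measures that require terminating the animal (liver content, flux
#' tests) are cross-sectional; cohorts are compared with one-way ANOVA or,
#' when a nonparametric test is indicated, a Kruskal-Wallis test, followed
#' by all-pairs comparisons adjusted by Tukey-Kramer. The nonparametric
#' branch uses a Nemenyi-type studentized-range test on mean ranks
#' (Conover-style large-sample approximation).
#'
#' @param values Numeric measurements.
#' @param group Group labels (same length).
#' @param test `"anova"` or `"kruskal_wallis"`.
#' @return A list of class `comparison_result`: `test`, `statistic`,
#'   `p_value`, and a `pairwise` tibble of adjusted p-values.
#' @export
compare_groups <- function(values, group, test = c("anova",
                                                   "kruskal_wallis")) {
  test <- match.arg(test)
  group <- factor(group)
  stopifnot(length(values) == length(group))
  n_i <- table(group)
  if (nlevels(group) < 2 || any(n_i < 2)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  k <- nlevels(group)
  if (test == "anova") {
    fit <- aov(values ~ group)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    pairwise <- tibble::tibble(
      pair = rownames(tk), diff = tk[, "diff"], adj_p = tk[, "p adj"])
    omnibus <- list(statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1])
  } else {
    kw <- kruskal.test(values, group)
    N <- length(values)
    r <- rank(values)
    rbar <- tapply(r, group, mean)
    ties <- table(r)
    tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
    pairs <- utils::combn(levels(group), 2)
    pairwise <- tibble::tibble(
      pair = apply(pairs, 2, paste, collapse = "-"),
      diff = apply(pairs, 2, function(pr) rbar[pr[2]] - rbar[pr[1]]),
      adj_p = apply(pairs, 2, function(pr) {
        se <- sqrt(N * (N + 1) / 12 * tie_corr *
                     (1 / n_i[pr[1]] + 1 / n_i[pr[2]]))
        q <- abs(rbar[pr[1]] - rbar[pr[2]]) / se * sqrt(2)
        ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
      }))
    omnibus <- list(statistic = unname(kw$statistic), p_value = kw$p.value)
  }
  structure(list(test = test, statistic = omnibus$statistic,
                 p_value = omnibus$p_value, pairwise = pairwise),
            class = "comparison_result")
}

#' Correlation of median food intake with maximum attained body weight
#'
#' Per animal: the median of its daily food intake series and the maximum
#' body weight it reached over the observed weeks (no smoothing). The
#' Pearson correlation between the two is reported, optionally excluding
#' animals flagged as dropouts.
#'
#' @param records A `long_records` tibble containing `food_g_day` and
#'   `bw_g` series.
#' @param cohort_weeks Optional cohort filter (e.g. 13).
#' @param include_dropouts Keep dropout animals.
#' @return List with `rho`, `p_value`, `n_animals`.
#' @export
intake_weight_correlation <- function(records, cohort_weeks = NULL,
                                      include_dropouts = TRUE) {
  d <- records
  if (!is.null(cohort_weeks)) d <- d[d$cohort_weeks %in% cohort_weeks, ]
  if (!include_dropouts) d <- d[!d$dropout, ]
  intake <- tapply(d$value[d$variable == "food_g_day"],
                   d$animal_id[d$variable == "food_g_day"], median)
  maxbw <- tapply(d$value[d$variable == "bw_g"],
                  d$animal_id[d$variable == "bw_g"], max)
  ids <- intersect(names(intake), names(maxbw))
  if (length(ids) < 3) stop("need >= 3 animals with both series",
                            call. = FALSE)
  x <- intake[ids]; y <- maxbw[ids]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant vector; correlation undefined", call. = FALSE)
  }
  ct <- cor.test(x, y)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       n_animals = length(ids))
}

#' Sensitivity of a trajectory fit to dropout animals
#'
#' Refits the polynomial mixed model with and without the records of
#' prematurely terminated animals and reports each fixed coefficient's
#' change in units of its (full-data) standard error. Under dropout
#' unrelated to outcome the deltas should be well below 1 SE.
#'
#' @param records A `long_records` tibble with dropout flags.
#' @param variable,degree,transform,random As in [fit_polynomial_lmm()].
#' @return List with `fit_all`, `fit_excluded`, and `delta_se` (per
#'   coefficient).
#' @export
dropout_sensitivity <- function(records, variable, degree,
                                transform = c("identity", "sqrt"),
                                random = c("slope", "intercept")) {
  transform <- match.arg(transform)
  random <- match.arg(random)
  fit_all <- fit_polynomial_lmm(records, variable, degree,
                                transform = transform, random = random,
                                include_dropouts = TRUE)
  if (!any(records$dropout)) {
    warning("no dropout animals present; fits are identical",
            call. = FALSE)
    return(list(fit_all = fit_all, fit_excluded = fit_all,
                delta_se = setNames(rep(0, degree + 1),
                                    paste0("b", 0:degree))))
  }
  fit_ex <- fit_polynomial_lmm(records, variable, degree,
                               transform = transform, random = random,
                               include_dropouts = FALSE)
  delta <- (fit_ex$fixed_coeffs - fit_all$fixed_coeffs) / fit_all$fixed_se
  list(fit_all = fit_all, fit_excluded = fit_ex,
       delta_se = setNames(delta, paste0("b", 0:degree)))
}
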