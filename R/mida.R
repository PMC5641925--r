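#' Precursor enrichment from the excess M2/M1 ratio
#'
#' For a polymer of `n` identical units drawing label independently with
#' probability `p`, the excess isotopomer abundances are binomial, so
#' `EM2/EM1 = ((n - 1)/2) * p/(1 - p)`. Inverting: with `R = EM2/EM1`,
#' `p = 2R / ((n - 1) + 2R)`. This is the core of mass-isotopomer
#' distribution analysis: the ratio fixes the precursor (acetyl-CoA)
#' enrichment without knowing what fraction of the pool is newly made.
#'
#' @param excess Excess MID vector (index 1 = M0).
#' @param n_units Number of precursor units in the polymer.
#' @return Precursor enrichment `p` in [0, 0.5).
#' @export
estimate_precursor_p <- function(excess, n_units) {
  stopifnot(length(excess) >= 3, n_units >= 2)
  excess <- unname(excess)
  em1 <- excess[2]; em2 <- excess[3]
  if (em1 <= 0) stop("no labeling detected (excess M1 <= 0)", call. = FALSE)
  if (em2 <= 0) return(0)
  R <- em2 / em1
  p <- 2 * R / ((n_units - 1) + 2 * R)
  if (p >= 0.5) {
    stop("M2/M1 ratio implies precursor enrichment >= 0.5; ",
         "inconsistent with a single-label binomial model", call. = FALSE)
  }
  p
}

#' Fractional de novo synthesis from excess M1
#'
#' `f = EM1 / A1(p)` where `A1(p) = n p (1 - p)^(n - 1)` is the M1
#' abundance of a 100% newly synthesized polymer pool at precursor
#' enrichment `p`. M1 carries the strongest signal; the analogous
#' EM2-based estimate is returned as a QC diagnostic — the two agree when
#' the binomial model holds.
#'
#' @param excess Excess MID vector (index 1 = M0).
#' @param p Precursor enrichment, in (0, 0.5).
#' @param n_units Number of precursor units.
#' @return Fractional synthesis `f_dnl`, with attribute `f_from_m2`.
#' @export
fractional_dnl <- function(excess, p, n_units) {
  excess <- unname(excess)
  if (all(excess[-1] == 0)) return(0)
  stopifnot(p > 0, p < 0.5)
  a1 <- n_units * p * (1 - p)^(n_units - 1)
  if (a1 < 1e-12) stop("M1 basis abundance below numeric floor", call. = FALSE)
  f <- excess[2] / a1
  a2 <- choose(n_units, 2) * p^2 * (1 - p)^(n_units - 2)
  structure(f, f_from_m2 = if (length(excess) >= 3) excess[3] / a2)
}

#' Split C18 labeling into de novo synthesis and chain elongation
#'
#' Stearate (and oleate, which keeps the stearate carbon skeleton) can be
#' made entirely de novo (9 labeled-or-not units, Binomial(9, p)) or by
#' elongating pre-existing palmitate with a single new unit
#' (Binomial(1, p)). The excess MID is decomposed onto those two binomial
#' basis columns by nonnegative least squares over the labeled channels
#' (M1 and up; M0 also contains the untouched pool and is excluded).
#'
#' @param excess_c18 Excess MID of the C18 analyte (index 1 = M0).
#' @param p Precursor enrichment, from palmitate of the same sample.
#' @return List with `f_dnl`, `f_elong` and `residual` (fit norm).
#' @export
decompose_elongation <- function(excess_c18, p) {
  stopifnot(length(excess_c18) >= 3)
  excess_c18 <- unname(excess_c18)
  if (p <= 1e-6 || p >= 0.5) {
    stop("mixture basis is singular or invalid at p = ", p, call. = FALSE)
  }
  k <- min(length(excess_c18) - 1L, 9L)
  basis <- cbind(dnl = dbinom(1:k, 9, p),
                 elong = dbinom(1:k, 1, p))
  y <- excess_c18[2:(k + 1L)]
  fit <- pracma::lsqnonneg(basis, y)
  f <- as.numeric(fit$x)
  if (sum(f) > 1 + 1e-6) {
    warning("f_dnl + f_elong exceeds 1; inconsistent excess MID",
            call. = FALSE)
  }
  list(f_dnl = f[1], f_elong = f[2],
       residual = sqrt(sum((basis %*% f - y)^2)))
}

#' Full MIDA workup of a measured fatty-acid MID
#'
#' Deconvolves the measured MID with the fragment's natural-abundance
#' correction matrix, then estimates precursor enrichment and fractional
#' synthesis; for C18 analytes the elongation split is applied using the
#' palmitate-derived `p` when supplied.
#'
#' @param measured Measured MID fractions.
#' @param fragment_formula Fragment elemental formula.
#' @param n_units Precursor units of the fully de novo polymer.
#' @param p_precursor Optional precursor enrichment from palmitate; when
#'   given, the elongation decomposition is used.
#' @param skeleton_correction Passed to [build_correction_matrix()].
#' @return List with `p`, `f_dnl`, `f_elong`, `excess` and `residual`.
#' @export
mida_workup <- function(measured, fragment_formula, n_units,
                        p_precursor = NULL, skeleton_correction = TRUE) {
  C <- build_correction_matrix(fragment_formula, n_labels = n_units,
                               shift = 1L,
                               skeleton_correction = skeleton_correction)
  dec <- deconvolve_mid(measured, C)
  excess <- dec$excess
  if (is.null(p_precursor)) {
    p <- estimate_precursor_p(excess, n_units)
    f <- fractional_dnl(excess, p, n_units)
    list(p = p, f_dnl = as.numeric(f), f_elong = 0,
         f_from_m2 = attr(f, "f_from_m2"),
         excess = excess, residual = dec$residual)
  } else {
    el <- decompose_elongation(excess, p_precursor)
    list(p = p_precursor, f_dnl = el$f_dnl, f_elong = el$f_elong,
         excess = excess, residual = dec$residual)
  }
}
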