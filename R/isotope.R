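#' Standard terrestrial isotope abundances
#'
#' Representative isotopic composition (IUPAC 2013 values) for the elements
#' found in derivatized metabolite fragments. Each entry is a numeric
#' vector of abundances indexed by nominal mass offset from the
#' monoisotopic species (offset 0, 1, 2, ...).
#'
#' @return Named list of abundance vectors.
#' @export
natural_abundances <- function() {
  list(
    C  = c(0.9893, 0.0107),
    H  = c(0.999885, 0.000115),
    N  = c(0.99636, 0.00364),
    O  = c(0.99757, 0.00038, 0.00205),
    Si = c(0.92223, 0.04685, 0.03092),
    S  = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Parse an elemental formula
#'
#' @param formula String such as `"C17H34O2"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)
  parts <- regmatches(formula, m)[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  el <- sub("[0-9]*$", "", parts)
  n <- sub("^[A-Z][a-z]?", "", parts)
  n <- ifelse(nzchar(n), as.integer(n), 1L)
  known <- names(natural_abundances())
  if (any(!el %in% known)) {
    stop("unknown element(s): ", paste(setdiff(el, known), collapse = ", "),
         call. = FALSE)
  }
  counts <- tapply(n, factor(el, levels = unique(el)), sum)
  setNames(as.integer(counts), names(counts))
}

conv <- function(a, b) {
  n <- length(a) + length(b) - 1
  out <- numeric(n)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

conv_pow <- function(a, n) {
  out <- 1
  for (i in seq_len(n)) out <- conv(out, a)
  out
}

#' Natural-abundance isotopologue pattern of a molecule
#'
#' Convolves the per-atom isotope distributions of every atom in the
#' formula, yielding the probability of each nominal mass offset M0, M1,
#' ... . The tail is truncated once the cumulative probability reaches
#' `1 - trunc_tol`.
#'
#' @param formula Elemental formula string, or a named count vector from
#'   [parse_formula()].
#' @param abundances Abundance table, by default [natural_abundances()].
#' @param trunc_tol Truncation tolerance for the distribution tail.
#' @return Numeric vector of isotopologue fractions (M0 first).
#' @export
isotope_pattern <- function(formula, abundances = natural_abundances(),
                            trunc_tol = 1e-6) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  pat <- 1
  for (el in names(counts)) {
    if (counts[[el]] > 0) {
      pat <- conv(pat, conv_pow(abundances[[el]], counts[[el]]))
    }
  }
  keep <- which(cumsum(pat) < 1 - trunc_tol)
  k <- if (length(keep)) max(keep) + 1L else 1L
  pat[seq_len(min(k, length(pat)))]
}

#' Natural-abundance correction matrix for a labeled fragment
#'
#' Column `j` (0-based label count) holds the isotopologue pattern of the
#' fragment carrying `j` tracer labels, shifted down by `j * shift` mass
#' units. With `skeleton_correction = TRUE` the `j` labeled positions are
#' removed from the natural-abundance computation of the tracer element
#' (a labeled position cannot also draw a natural heavy isotope); without
#' it all positions keep their natural distribution. Multiplying this
#' matrix by a tracer-incorporation distribution reproduces the measured
#' MID; deconvolution inverts that map.
#'
#' @param formula Fragment elemental formula.
#' @param n_labels Maximum number of tracer labels, >= 1.
#' @param shift Nominal mass shift per label (1 for 13C, 2 for D2).
#' @param tracer_element Element whose positions carry the label
#'   (default `"C"` for shift 1, `"H"` for shift 2).
#' @param skeleton_correction Remove labeled positions from the
#'   natural-abundance convolution of the tracer element.
#' @param abundances Abundance table.
#' @return Matrix of class `correction_matrix` with `n_labels + 1` columns.
#' @export
build_correction_matrix <- function(formula, n_labels, shift = 1L,
                                    tracer_element = if (shift == 1) "C"
                                                     else "H",
                                    skeleton_correction = TRUE,
                                    abundances = natural_abundances()) {
  stopifnot(n_labels >= 1, shift %in% c(1L, 2L))
  counts <- parse_formula(formula)
  n_sub_per_label <- if (shift == 2 && tracer_element == "H") 2L else 1L
  max_sub <- n_labels * n_sub_per_label
  if (!tracer_element %in% names(counts) ||
      counts[[tracer_element]] < max_sub) {
    stop("formula has fewer ", tracer_element,
         " atoms than labelable positions", call. = FALSE)
  }
  cols <- vector("list", n_labels + 1L)
  for (j in 0:n_labels) {
    cj <- counts
    if (skeleton_correction) {
      cj[[tracer_element]] <- cj[[tracer_element]] - j * n_sub_per_label
    }
    pat <- isotope_pattern(cj, abundances = abundances)
    cols[[j + 1L]] <- c(rep(0, j * shift), pat)
  }
  nrow_out <- max(vapply(cols, length, 1L))
  C <- vapply(cols, function(x) c(x, rep(0, nrow_out - length(x))),
              numeric(nrow_out))
  rownames(C) <- paste0("M", 0:(nrow_out - 1))
  colnames(C) <- paste0("lab", 0:n_labels)
  structure(C, class = c("correction_matrix", "matrix"), shift = shift)
}

#' Deconvolve a measured MID into a tracer-incorporation distribution
#'
#' Solves `measured = C %*% excess` by nonnegative least squares, which is
#' robust to truncated m/z acquisition windows (e.g. m0-m4 of glucose
#' pentaacetate) where plain matrix inversion is not. The measured vector
#' may be shorter than the matrix; rows beyond the window are dropped.
#'
#' @param measured Measured MID fractions (M0 first).
#' @param C A [build_correction_matrix()] result.
#' @param cond_limit Condition-number cutoff for the (windowed) matrix.
#' @return List with `excess` (nonnegative fractions per label count) and
#'   `residual` (Euclidean norm of the fit residual).
#' @export
deconvolve_mid <- function(measured, C, cond_limit = 1e8) {
  stopifnot(is.numeric(measured), length(measured) >= ncol(C))
  n <- min(length(measured), nrow(C))
  Cw <- C[seq_len(n), , drop = FALSE]
  if (kappa(Cw, exact = TRUE) > cond_limit) {
    stop("correction matrix is ill-conditioned over the measured window",
         call. = FALSE)
  }
  fit <- pracma::lsqnonneg(Cw, measured[seq_len(n)])
  excess <- as.numeric(fit$x)
  names(excess) <- colnames(C)
  list(excess = excess,
       residual = sqrt(sum((Cw %*% excess - measured[seq_len(n)])^2)))
}
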