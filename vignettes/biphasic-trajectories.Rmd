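---
title: "Models and methods: biphasic trajectories and isotope fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: biphasic trajectories and isotope fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biphasica)
```

`biphasica` analyzes a 6-month diet-intervention design in mice: staggered
cohorts (defaults 20/19/20/30 animals terminated at 4/9/13/28 weeks on
diet, plus a small dedicated glucose-turnover arm of 16 animals tested at
weeks 3/9/15/27), longitudinal blood sampling every 4 weeks, and terminal
flux measurements that consume the animal. This vignette documents the
models, the numerical choices, and what the synthetic-data validation does
and does not demonstrate.

## The trajectory model

For a longitudinal variable $y_{ij}$ (animal $i$, week $t_{ij}$) the
package fits

$$y_{ij} = \sum_{k=0}^{d}\beta_k t_{ij}^k + b_{0i} + b_{1i}t_{ij} +
  \varepsilon_{ij},\qquad d \in \{1,2,3\},$$

by maximum likelihood (`lme4`). The per-animal random intercept and linear
slope with unstructured 2×2 covariance is the minimal structure that can
reproduce the situation these studies show — conditional R² far above
marginal R² — while staying estimable from 2–8 observations per animal.
When that fit is singular (common in short cohorts, where slope variance is
weakly identified) the model falls back to a random intercept only; the
result records the fallback. ML rather than REML is used throughout so
nested fixed-effect models are comparable by likelihood ratio; the small
downward bias in variance components at these sample sizes (≥ 89 animals)
is negligible relative to the ±0.05 recovery tolerance used in validation.

Degree is selected by nested LRTs (1 df each, α = 0.05 by default),
escalating linear → quadratic → cubic while the added term is significant.
AIC per candidate is reported alongside so either criterion is auditable.
The selection statistic and the random-effects structure are the package's
own choices: "best fit" can be operationalized several ways, and this one
is declared rather than inferred.

Right-skewed concentrations (plasma TG) are fit on the square-root scale,
the usual variance-stabilizing transform for such data. A strictly
monotone transform preserves extremum *location*, so peak weeks are
computed on the transform scale without back-transformation; fitted curves
can be squared for display.

**Numerical conditioning.** Weeks enter the design matrix scaled by 1/10
(so a cubic term at week 28 is ~22 rather than ~22000); coefficients, SEs
and variance components are rescaled to the weeks scale before being
returned.

**R² decomposition.** With
$\mathrm{var}_{fixed}$ = population variance of the fixed-effect
predictions over the observed design points,
$\mathrm{var}_{random}$ = the average over observations of
$\sigma_{b_0}^2 + 2\sigma_{b_0b_1}t + \sigma_{b_1}^2t^2$ (random slopes
make this design-dependent; averaging over the realized design is the
package's resolution of that ambiguity), and
$\mathrm{var}_{resid} = \sigma^2$:

$$R^2_m = \frac{\mathrm{var}_{fixed}}{\mathrm{var}_{fixed} +
\mathrm{var}_{random} + \mathrm{var}_{resid}},\qquad
R^2_c = \frac{\mathrm{var}_{fixed} + \mathrm{var}_{random}}
{\mathrm{var}_{fixed} + \mathrm{var}_{random} + \mathrm{var}_{resid}}.$$

**Peak localization.** Stationary points of the fixed polynomial are the
analytic roots of its derivative, classified by the second derivative. By
default the search is restricted to the observed week range; a qualifying
root outside it is still returned but flagged `in_range = FALSE` — a
fitted trough at a negative week is a meaningful statement (the curve only
rises within the study window), not an error.

## The synthetic cohort

`simulate_trajectories()` generates exactly the structure the fitter
assumes: polynomial group-mean curve, Gaussian random intercepts/slopes,
Gaussian residuals, optional sqrt-scale simulation (values squared back),
staggered cohort truncation, and MCAR dropout — a randomly chosen 10/115
fraction of animals truncated at a uniform random week. Real attrition in
such studies is tied to weight loss and may be informative; independence
is chosen deliberately so that the dropout sensitivity check has a clean
null, and the informative-dropout case is exercised separately in the test
suite by construction.

Helper constructors place extrema exactly: `cubic_peak_coeffs(w, w', b, h)`
builds the cubic whose derivative has roots at `w` and `w'` with the
extremum displaced `h` from baseline, and `quadratic_vertex_coeffs()` the
parabola with a given vertex. Noise conventions used by the recovery
experiments, with $S$ the range of the fixed curve over the sampled weeks:
random intercept SD $0.2S$, random slope SD $0.05S/28$ per week (so an
animal's slope deviation contributes 5% of signal by the last week — the
"5% of signal" convention is interpreted as an end-of-study contribution),
residual SD $0.1S$. For the small quadratic arm both intercept and
residual SDs are $0.1S$. These were fixed once, from the qualitative
description of the cohorts (large heterogeneity, conditional R² ≫
marginal R²), and define the validation conditions.

Because generators return their ground truth, estimator quality is stated
as parameter recovery: noiseless inputs must be recovered exactly (to
solver tolerance) and noisy inputs within Monte-Carlo error. Problem sizes
used in the recovery experiments — 100 animals × 20 replicates for the
cubic peaks and R², 16 animals × 50 replicates for the quadratic troughs —
were chosen so that the Monte-Carlo standard error of the mean recovered
quantity is several times smaller than the tolerance being checked.

What passing recovery shows: the estimators are consistent and essentially
unbiased *under the model they assume*. What it does not show: robustness
to non-Gaussian animal effects, informative dropout, assay drift between
cohorts, or model misspecification (e.g. a true plateau rather than a
polynomial peak). The cubic is a description of curvature within the
window, not a mechanistic growth law.

## Isotope machinery

**Natural-abundance correction.** `isotope_pattern()` convolves per-atom
isotope distributions (IUPAC 2013 representative abundances, frozen in
`natural_abundances()` for reproducibility) over an elemental formula,
truncating the tail at cumulative $1-10^{-6}$. `build_correction_matrix()`
stacks shifted patterns of the fragment carrying $j$ tracer labels; by
default labeled positions are removed from the natural-abundance
convolution of the tracer element (skeleton correction — the main point on
which correction-matrix constructions differ; a toggle is provided).
Deconvolution uses nonnegative least squares (`pracma::lsqnonneg`) rather
than matrix inversion so truncated acquisition windows — such as the
m0–m4 window of glucose pentaacetate — remain solvable, with the matrix
condition number checked first.

**MIDA.** For a polymer of $n$ acetyl units ($n=8$ for palmitate, 9 for
stearate made de novo) at precursor enrichment $p$, excess isotopomers are
binomial. $p$ is estimated from $EM_2/EM_1$, which is independent of the
fraction of pool renewed; fractional synthesis from
$f = EM_1/(np(1-p)^{n-1})$ ($EM_1$ carries the most signal; the
$EM_2$-based estimate is attached as a QC diagnostic since the two agree
only when the binomial model holds). C18 excess MIDs are decomposed as a
nonnegative mixture of Binomial(9, p) (de novo) and Binomial(1, p)
(elongation of pre-existing palmitate) over channels M1 and up — M0 also
contains the untouched pool and is excluded from the fit. Oleate shares
the stearate basis (desaturation conserves the carbon skeleton). A single
mass shift per label is the default, matching a singly labeled acetate
tracer; a 2-Da shift is supported for doubly labeled tracers.

**Glucose turnover.** The tracer concentration series (enrichment ×
tracee, quasi-steady tracee taken as the mean measured glucose) is fit to
the Bateman curve by Levenberg–Marquardt over a 3×3 multistart grid, with
$k_a = k_e + e^{\delta}$ enforcing order and removing the
role-swap ambiguity of the two exponentials. Moments are closed-form:
$AUC = A(1/k_e - 1/k_a)$, $AUMC = A(1/k_e^2 - 1/k_a^2)$,
$MRT = AUMC/AUC$; then $MCR = F\,\mathrm{dose}/AUC$ per kg,
$V_d = MCR \times MRT$ (an internal identity, tested as such), pool
$= V_d [\mathrm{glucose}]$, $EGP = MCR \times [\mathrm{glucose}]$, with
mg ↔ µmol via 180.16 g/mol. After an intraperitoneal bolus, absolute
bioavailability cannot be identified without an intravenous reference
arm, so $F = 1$ by default and clearance/volume outputs are *apparent*;
MRT includes the absorption phase (an IV-referenced MRT would subtract
$1/k_a$). Both caveats are stamped into the output. Insulin-sensitivity
indices (overall $1/(G\cdot I)$, peripheral $MCR/I$, hepatic
$1/(EGP\cdot I)$) follow common mouse-tracer practice; the definitions
travel with the result so downstream tables are self-describing.

**VLDL-TG secretion.** OLS slope of TG vs time × theoretical plasma
volume, 75 mL/kg × (1 − 0.45) = 41.25 mL/kg. Plasma (not blood) volume is
used because the slope is measured in plasma TG concentration. The
pre-injection baseline is included in the regression by default — it
anchors the intercept at no cost under linear accumulation — and can be
excluded, since protocols differ on this point. A negative slope is
returned with a warning flag rather than an error (it indicates a failed
lipase block, which the analyst should see, not a crash).

**Sterol balance.** Bile flow = weighed bile mass / 20 min at density
1.0 g/mL (bile is weighed, density is an assumption; overridable).
Secretion and excretion rates are bilinear products normalized per 100 g
body weight, the field's convention — the normalization basis is
configuration, not measurement.

## Group statistics

Cross-sectional cohort comparisons use one-way ANOVA with Tukey–Kramer
HSD, or Kruskal–Wallis followed by a Nemenyi-type studentized-range test
on mean ranks (with tie correction). The rank-based post hoc is a
large-sample approximation chosen because "Kruskal–Wallis with
Tukey–Kramer correction" admits several constructions; this one is
documented as the package's choice. Its family-wise error calibration is
verified by simulation in the test suite.

The intake–weight analysis correlates each animal's median daily food
intake with its maximum attained body weight (no smoothing), Pearson, with
dropout animals includable or excludable. The dropout sensitivity check
refits a trajectory model with and without dropout animals' records and
reports coefficient deltas in SE units; under MCAR dropout at the design
rate these stay well below 1 SE.

## Degenerate inputs and tie-breaks

- Quadratic fits with $\beta_2 = 0$ (to numerical tolerance) raise a
  degenerate-polynomial error from `locate_extremum()` rather than
  returning an arbitrary root.
- When several stationary points of the requested kind fall in range, the
  one nearest the window midpoint is returned (cubics can have at most one
  of each kind, so this matters only for pathological inputs).
- `non_hdl_c()` permits negative differences (assay noise) with a warning
  instead of clipping, so downstream averages are not biased upward.
- MID vectors are validated to sum to 1 within $10^{-9}$ before noise;
  noisy simulated MIDs are truncated to [0, 1] and renormalized, as a real
  preprocessing chain would.
- `estimate_precursor_p()` refuses ratios implying $p \ge 0.5$, where the
  single-label binomial inversion loses identifiability.

## Known limitations

- The trajectory model assumes Gaussian random effects and residuals;
  heavy-tailed heterogeneity will widen recovery error beyond the quoted
  Monte-Carlo bands.
- Dropout is modeled as MCAR; joint modeling of dropout and outcome is
  out of scope.
- The LRT degree selection compares fits that may differ in random-effects
  fallback status in edge cases; the selection trace records both fits'
  log-likelihoods so such cases are visible.
- Bioavailability, and therefore absolute MCR/Vd after IP dosing, is not
  identifiable from these data alone.
- No instrument-level processing: the package starts from measured MID
  vectors and concentration series, not spectra or chromatograms.
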