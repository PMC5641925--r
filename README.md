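# biphasica

Biphasic trajectory and stable-isotope flux analysis for longitudinal
diet-intervention studies in mice.

Long-running high-fat/high-cholesterol feeding studies produce two kinds of
data: truly longitudinal series (body weight, plasma lipids, glucose,
insulin, sampled per animal every 4–6 weeks across staggered cohorts) and
terminal flux measurements that can be made only once per animal (VLDL-TG
secretion, de novo lipogenesis, endogenous glucose production, biliary and
fecal sterol output). Many of these variables do not change monotonically —
they rise, peak somewhere mid-study and fall again — and between-animal
heterogeneity is large enough that the group mean alone is a poor summary.
`biphasica` implements the full computational chain for such a study, and,
because animal-level data of this kind are rarely public, ships a
synthetic-cohort generator with known ground truth so that every estimator
in the chain can be validated by parameter recovery.

## What the package computes

**Polynomial linear mixed models.** For a variable $y_{ij}$ measured on
animal $i$ at week $t_{ij}$,

$$y_{ij} = \beta_0 + \beta_1 t_{ij} + \beta_2 t_{ij}^2 + \beta_3 t_{ij}^3
  + b_{0i} + b_{1i} t_{ij} + \varepsilon_{ij},$$

with per-animal random intercepts and slopes
$(b_{0i}, b_{1i}) \sim N(0, \Sigma)$ and
$\varepsilon_{ij} \sim N(0, \sigma^2)$. The degree (linear vs biphasic
quadratic/cubic) is chosen by nested likelihood-ratio tests on ML fits;
right-skewed variables can be fit on the square-root scale. Variance is
decomposed as

$$R^2_{marginal} = \frac{\mathrm{var}_{fixed}}
   {\mathrm{var}_{fixed} + \mathrm{var}_{random} + \mathrm{var}_{resid}},
\qquad
R^2_{conditional} = \frac{\mathrm{var}_{fixed} + \mathrm{var}_{random}}
   {\mathrm{var}_{fixed} + \mathrm{var}_{random} + \mathrm{var}_{resid}},$$

and the week of the fixed-effect peak or trough is found from the
analytic roots of the fitted polynomial's derivative. Per-animal curves are
available as BLUP-adjusted trajectories.

**Stable-isotope fluxes.**

- *VLDL-TG secretion*: after poloxamer 407 blocks lipoprotein lipase,
  plasma TG rises linearly; secretion = OLS slope (mM/h) × theoretical
  plasma volume (75 mL/kg blood × (1 − 0.45) hematocrit = 41.25 mL/kg),
  in µmol TG/kg/h.
- *De novo lipogenesis (MIDA)*: natural-abundance correction matrices are
  built from elemental formulas and measured mass-isotopomer distributions
  are deconvolved by nonnegative least squares; precursor enrichment comes
  from the binomial ratio $EM_2/EM_1 = \frac{n-1}{2}\frac{p}{1-p}$,
  fractional synthesis from $f = EM_1 / (n p (1-p)^{n-1})$, and C18
  labeling is split into de novo (Binomial(9, p)) and chain-elongation
  (Binomial(1, p)) components.
- *Endogenous glucose production*: a [6,6]-D₂-glucose bolus enrichment
  curve is fit to the Bateman form
  $A(e^{-k_e t} - e^{-k_a t})$; closed-form moments give AUC, MRT,
  clearance MCR = dose/AUC, $V_d$ = MCR × MRT, and at steady state
  EGP = MCR × [glucose]. Insulin-sensitivity indices are derived from MCR,
  EGP, glucose and insulin.
- *Sterol balance*: bile flow from weighed 20-min collections and
  secretion/excretion rates as flow (or fecal mass rate) × concentration
  per 100 g body weight.

**Group statistics.** Cross-sectional cohort comparisons by one-way ANOVA
or Kruskal–Wallis with Tukey–Kramer-adjusted all-pairs tests, the
intake-vs-maximum-weight correlation, and a dropout sensitivity check that
refits trajectory models with and without prematurely terminated animals.

## Worked example

Simulate a TG-like cohort whose true fixed-effect maximum is at week 18,
fit the cubic mixed model on the square-root scale and locate the peak:

```r
library(biphasica)

beta  <- cubic_peak_coeffs(18, 2, baseline = 1, height = 0.8)
S     <- diff(range(sapply(seq(0, 28, 4), function(t) sum(beta * t^(0:3)))))
truth <- trajectory_truth(beta, random_sd = c(0.2 * S, 0.05 * S / 28),
                          resid_sd = 0.1 * S, transform = "sqrt")
sim   <- simulate_trajectories(
  cohort_design(sizes = 100, termination_weeks = 28, dropout_rate = 0,
                seed = 1),
  truth, variable = "tg_mM")

fit <- fit_polynomial_lmm(sim$records, "tg_mM", degree = 3,
                          transform = "sqrt")
locate_extremum(fit, "maximum")$week
#> [1] 18.00074
fit$r2
#>    marginal_r2 conditional_r2
#>      0.6920730      0.9148486
```

The peak lands within a fraction of a week of the true value, and the
conditional R² far exceeds the marginal one — most variance sits between
animals, exactly the situation the random-effects structure is there for.

The full analysis workflow lives under `analysis/` as numbered stages
(`01_simulate_cohort.R` → `04_sterol_balance.R`); each stage prints a short
summary and writes its tables under `results/`.

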