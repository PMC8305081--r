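---
title: "Modelling lactic fermentation kinetics and starter-culture effects with fermkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lactic fermentation kinetics and starter-culture effects with fermkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

## The scientific setting

Spontaneous lactic fermentation of a cereal slurry — here pearl millet,
the base of traditional non-alcoholic beverages such as *kunun-zaki* —
is driven by lactic acid bacteria (LAB) converting sugars to lactic
acid. Three families of quantities describe the process at the bench:
acidification (pH falling, titratable acidity rising), soluble sugar
(glucose released by amylolysis faster than it is consumed early on),
and microbial load (LAB and total viable count, TVC, on the log10
CFU/mL scale). fermkin implements the primary models for all three, the
factorial analysis used to choose starter cultures for a controlled
fermentation, and Monte Carlo propagation of inoculum uncertainty
through the fitted response models.

All fitting works from *summary tables* — per-time (or per-run) mean,
standard deviation and replicate count — because that is what is
reported and archived in practice. Two such tables ship with the
package (`ferm_fixture("slurry_timecourse")`, a 36 h / 13-point
triplicate time course, and `ferm_fixture("starter_design")`, a
2^3 + centre inoculum experiment).

## Acidification: the exponential model

pH and titratable acidity (TTA, % lactic acid) follow

$$y(t) = a - b\,e^{-ct},$$

with $a$ the horizontal asymptote, $b = a - y(0)$, and $c$ the rate
constant (h$^{-1}$). For pH, $b$ is negative (the curve falls to $a$
from above); for TTA it is positive. The model is empirical: it
summarises the saturation of acid production as substrate is consumed
and acid stress builds, without mechanistic claims.

```{r}
ts <- ferm_fixture("slurry_timecourse")
fit_exponential(ts$time_h, ts_means(ts, "ph"))
```

Fitting is Levenberg–Marquardt least squares (via minpack.lm) with a
deterministic multi-start ladder on the rate constant: the default
start takes $a$ at the last observation, $b = a - y_1$, $c = 0.1$
h$^{-1}$, and up to 20 restarts scale the rate start by fixed factors
between 0.02 and 25. The best-RSS solution is kept; the rate is bounded
below at $10^{-8}$ so a converged fit always has $c > 0$. Convergence
tolerances are a relative RSS change below $10^{-10}$ or a parameter
step below $10^{-8}$. Standard errors come from the local
linearisation at the optimum, and $R^2 = 1 - \mathrm{RSS}/\mathrm{CSS}$
is computed on the fitted points (`r_squared()`), so a fit can score
negative $R^2$ when worse than the mean.

Fitting uses the per-time **means** by default. For balanced designs
this leaves point estimates identical to replicate-level fitting (a
property the test suite asserts); replicate-level or weighted fits are
available through the `weights` argument. No inverse-variance weighting
is applied by default: the per-time SDs of typical bench data are too
noisy (n = 3) to stabilise a weighting scheme, and the reference
analyses are unweighted.

Titratable acidity itself is derived from a titration reading by
`tta_percent()`: % lactic acid =
$\mathrm{mL\,NaOH} \times M \times 90.08 / (V_\mathrm{sample} \times 1000) \times 100$.

## Sugar: the quadratic model

Glucose (%) is fitted by ordinary least squares as
$c_0 + c_1 t + c_2 t^2$ — a rise while amylases outpace consumption,
then a flattening and decline. `fit_quadratic()` is a thin wrapper over
`lm()` that reports the same $R^2$ definition as above and refuses
rank-deficient time vectors.

## Growth: the modified Gompertz model

Counts are modelled on the log10 scale with the Zwietering-type
reparameterised Gompertz curve,

$$\log_{10} N(t) = K + A\exp\!\left\{-\exp\!\left[\frac{\mu_{\max} e\,(\lambda - t)}{A} + 1\right]\right\},$$

whose parameters are directly interpretable: $K$ the initial level, $A$
the rise to the stationary density, $\mu_{\max}$ the maximum growth
rate (Δlog10 CFU/mL per h), $\lambda$ the lag time (h). Closed-form
anchors used as test oracles: the value at $t = \lambda$ is
$K + A e^{-e}$, and the asymptote is $K + A$. The lag is constrained
non-negative; genuinely lag-free growth fits at the boundary
$\lambda = 0$. Monotone-decreasing count series have no admissible
rise: the fitter warns and returns the boundary fit (flat curve at the
mean) rather than chasing an interior optimum that does not exist.

Goodness of fit uses the mean relative deviation modulus

$$E\% = \frac{100}{n}\sum \frac{|O - P|}{O},$$

the convention in food microbiology (values below ~10% are read as
adequate). For the bundled TVC series, the published parameter set
$(K, A, \mu_{\max}, \lambda) = (6.911, 0.790, 0.202, 0)$ scores

```{r}
p <- ferm_reference_params()$tvc_log10cfu
pred <- eval_gompertz(ts$time_h, p["K"], p["A"], p["mu_max"], p["lag"])
e_percent(ts_means(ts, "tvc_log10cfu"), pred)
```

A note on the bundled reference parameters
(`ferm_reference_params()`): the published LAB row is internally
inconsistent — its printed rise $A = 0.092$ caps the curve a full log
below the observed counts. Refitting on the bundled means reproduces
the published $K$, $\mu_{\max}$ and $\lambda$ to print precision with
$A = 0.981$, so the package treats the printed $A$ as a typographic
error and stores the refit value.

A caveat on identifiability: with 13 points at 3 h spacing and a
~1-log rise, $\mu_{\max}$ and $\lambda$ are weakly determined — the
information bound puts their relative sampling error well above 10% at
replicate noise of 0.05 log. Recovery experiments should therefore be
judged against the design's own standard errors (as the test suite
does), not against a fixed percentage band.

## Plateau detection (optimum fermentation time)

`plateau_time()` returns the earliest sampling time from which **every**
later consecutive pair of time points fails a two-sample Welch
comparison at level `alpha` (default 0.05), with the Welch statistic
reconstructed from mean/sd/n. This is a deliberate simplification of
the multiple-range tests (MANOVA + Duncan grouping) used on raw
replicates at the bench, which cannot be reproduced from summary
tables. On the bundled pH series it returns 12 h with all pairwise
changes beyond 18 h clearly non-significant — consistent with an
optimum fermentation window of 12–18 h for this slurry. Consecutive
comparisons at a fixed `alpha` carry no multiplicity correction; the
result is a descriptive stabilisation point, not a confirmatory test.

## Starter-culture effects: the factorial response model

The starter experiment inoculates pasteurised extract with three
cultures at 0.05/0.10% w/w (2^3 corners, centre 0.075%) and measures
pH, TTA and viscosity after fermentation. `fit_factorial()` fits

$$Y = \beta_0 + \beta_1 x_1 + \beta_2 x_2 + \beta_3 x_3 + \beta_{12}x_1x_2 + \beta_{13}x_1x_3 + \beta_{23}x_2x_3\ (+\ \beta_{123}x_1x_2x_3)$$

by OLS on the cell means in **natural (uncoded) concentration units** —
the convention that matches the published coefficient magnitudes
(interactions in the tens to thousands); a coded ±1 parameterisation
would produce numbers of a different order entirely. The three-way term
is off by default and enabled for viscosity, where the joint-culture
effect is substantively real. Inference is Gaussian identity-link:
dispersion scale $= \mathrm{RSS}/\mathrm{dof}$, Wald 95% intervals with
the normal multiplier, two-sided normal p-values.

```{r}
d <- ferm_fixture("starter_design")
fit_factorial(d, "tta_pct")
```

Two reproducibility limits are inherent to cell-mean fitting and are
documented rather than patched: the original experiment's full
replication layout (19 runs) is not recoverable from the summary
table, so intercepts and dispersion scales — which are sensitive to
how centre replicates enter — are not expected to match published
values exactly, while all non-intercept coefficients are
replication-invariant for balanced designs and do match. Published
standard errors are similarly tied to the unrecoverable layout; this
package's standard errors are the correct ones for the cell-mean fit
it performs.

## Monte Carlo uncertainty and sensitivity

`monte_carlo()` draws inoculum triples i.i.d. uniform over each
culture's range — default [0.05, 0.10]%, the experimental range —
propagates them through a fitted (or supplied) response model with **no
residual noise added**, and summarises percentiles plus sensitivity.
Residual noise is deliberately excluded: the propagated distribution
answers "what does inoculum uncertainty alone do to the response", and
adding bench-level noise (e.g. pH sd ≈ 0.16) would roughly double the
spread and change the meaning of the reported percentiles.

Sensitivity is the per-factor Spearman rank correlation between draws
and predictions (the tornado-chart quantity; Pearson available), and a
contribution share defined as squared correlations normalised to sum
to 100% across the three factors. Normalisation to 100 is a design
choice: raw spreadsheet-style "contribution" percentages can exceed
100% and have no variance-decomposition interpretation, so the package
reports a quantity that does. Factor *ranking* is unaffected.

```{r}
ph_model <- factorial_coefficients(ferm_reference_glm()$ph)
monte_carlo(ph_model, n = 1000, seed = 1)
```

Determinism: every sampler takes an integer seed, identical seeds give
bitwise-identical summaries, and `run_all()` derives per-response seeds
as `seed + k` so a single pipeline seed fixes the whole report.

## Synthetic data generators

`synth_timeseries()` and `synth_design()` forward-simulate the models
above with i.i.d. Gaussian replicate noise and tabulate mean/sd/n —
the same summary shape as real data, enabling parameter-recovery tests
without any external input. Defaults are the reference conditions:
13 samplings at 3 h intervals, triplicates, truth at the reference
fitted parameters, and noise magnitudes matching the reference tables
(per-variable sd: pH 0.09, TTA 0.02, glucose 0.06, LAB 0.5, TVC 0.2 —
the pooled magnitude of the printed per-time SDs; design residual sd
= the square root of each response's published dispersion scale).
Gaussian noise is the natural reading of symmetric mean ± SD
reporting; noise is homoscedastic per variable by default with
per-time vectors accepted for stress tests.

What the generators deliberately do **not** emulate: the non-monotone
wiggles of real count data (successional waves of different genera,
death phases), heteroscedastic acidification noise, or correlated
errors across variables measured on the same aliquot. Passing recovery
tests therefore demonstrate estimator correctness under the stated
noise model, not robustness to structured biological deviation.

## Numerical choices and degenerate inputs

- Quantiles are linear-interpolation (type 7) order statistics.
- `r_squared()` refuses zero corrected sum of squares; `e_percent()`
  refuses non-positive observations (division domain).
- A constant response in the factorial fit returns zero coefficients
  and zero scale; rank-deficient designs are rejected naming the
  collinear terms; the saturated 8-term model on the 8 corners
  interpolates the corner means exactly (dof = 0, scale 0).
- Welch comparisons with two zero SDs degenerate to an exact
  equal/unequal decision.
- Multi-start ladders are deterministic (fixed factor sequences), so
  fits carry no hidden RNG state.

## Problem sizes

All analyses here are desk-scale: 13-point kinetic fits, 9-run OLS,
1000-case Monte Carlo, and recovery suites of 40–100 seeded replicates
each run in seconds on one core. These sizes match the reference
experiment; nothing in the implementation assumes them.

## Known limitations

- The exponential and quadratic models are empirical summaries;
  extrapolation beyond the observed window (especially the quadratic,
  which eventually predicts negative glucose) is unsupported.
- Plateau detection is a summary-statistics surrogate with no
  multiplicity control.
- Cell-mean GLM inference cannot reproduce replication-dependent
  quantities (intercepts, scales, standard errors) of analyses run on
  raw replicate layouts.
- The Monte Carlo sampler draws factors independently; correlated
  inoculum errors and variance-based (Sobol) decompositions are out of
  scope, as are secondary (temperature-dependent) growth models.
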