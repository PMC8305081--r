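# fermkin

Primary predictive-microbiology models for lactic acid fermentation of
cereal slurries, written for food scientists analysing bench
fermentations of traditional non-alcoholic beverages (pearl millet
*kunun-zaki* and relatives) from the summary tables such experiments
produce: per-time or per-run mean ± SD of triplicate readings.

The package covers, end to end:

- **Acidification kinetics** — `fit_exponential()` fits
  `y(t) = a − b·exp(−c·t)` to pH or titratable-acidity time courses
  (`a` asymptote, `c` rate constant in h⁻¹), with `R² = 1 − RSS/CSS`.
- **Sugar kinetics** — `fit_quadratic()` fits
  glucose% = c₀ + c₁t + c₂t² by OLS.
- **Microbial growth** — `fit_gompertz()` fits the modified
  (Zwietering-type) Gompertz curve
  `log₁₀N(t) = K + A·exp{−exp[μmax·e·(λ−t)/A + 1]}` on the log10
  CFU/mL scale, scored by the mean relative deviation modulus
  `E% = (100/n)·Σ|O−P|/O` (`e_percent()`).
- **Optimum fermentation time** — `plateau_time()` finds the earliest
  time from which consecutive samplings stop differing (Welch
  comparisons rebuilt from mean/sd/n).
- **Starter-culture effects** — `fit_factorial()` fits the factorial
  inoculum model `Y = β₀ + Σβᵢxᵢ + Σβᵢⱼxᵢxⱼ (+ β₁₂₃x₁x₂x₃)` in natural
  concentration units over a 2³+centre design, with Wald inference and
  a Gaussian dispersion scale.
- **Uncertainty propagation** — `monte_carlo()` pushes uniform inoculum
  uncertainty through a fitted model (no residual noise), reporting
  percentiles, tornado correlations and per-factor contribution shares.
- **Synthetic data** — `synth_timeseries()` / `synth_design()` generate
  seeded replicate datasets from known truth for recovery studies.
- **Pipeline** — `run_all()` chains every stage into a deterministic,
  JSON-serialisable report (`write_report_json()`); a thin CLI lives in
  `inst/cli/fermkin.R`.

Reference datasets from a published pearl-millet fermentation ship with
the package: `ferm_fixture("slurry_timecourse")` (36 h spontaneous
fermentation, 13 time points × 5 variables) and
`ferm_fixture("starter_design")` (2³+centre inoculum experiment with
*L. mesenteroides*, *P. pentosaceus*, *E. gallinarum*).

## Worked example

```r
library(fermkin)
ts <- ferm_fixture("slurry_timecourse")

fit_exponential(ts$time_h, ts_means(ts, "ph"))
#> Exponential acidification fit: y = a - b*exp(-c*t)
#>       a       b       c
#>  3.3823 -3.1879  0.0705
#> R2 = 0.9714 on 13 points
```

The slurry acidifies at 0.071 h⁻¹ towards an asymptotic pH of 3.38,
and the model explains 97.1% of the pH variation. The negative `b`
says the curve falls to the asymptote from the initial pH
`a − b ≈ 6.57`.

```r
plateau_time(ts, "ph")
#> [1] 12
pearson_matrix(ts, c("ph", "tta_pct"))$label["ph", "tta_pct"]
#> [1] "very strong, negative"
```

pH stops changing significantly between consecutive samplings from
12 h on (r = −0.983 with titratable acidity: acid production drives
the pH drop), supporting an optimum fermentation window well short of
the traditional 24–36 h.

```r
d <- ferm_fixture("starter_design")
coef(fit_factorial(d, "tta_pct"))["x1:x2"]
#> x1:x2
#>    32
```

The *L. mesenteroides* × *P. pentosaceus* interaction raises
titratable acidity by 32 %TTA per (% inoculum)² — the dominant synergy
in the design.

```r
ph_model <- factorial_coefficients(ferm_reference_glm()$ph)
monte_carlo(ph_model, n = 1000, seed = 1)
#> Monte Carlo propagation: 1000 cases (seed 1)
#> Percentiles:
#>     p1     p5    p50    p95    p99
#> 3.5414 3.5650 3.5984 3.6619 3.6963
#> Factor correlation (tornado):
#>      x1      x2      x3
#>  0.3016 -0.2039  0.6790
#> Contribution to variation (%):
#>    x1    x2    x3
#> 15.33  7.00 77.67
```

Under uniform inoculum uncertainty over the experimental range
(0.05–0.10% per culture), 95% of simulated batches stay at or below
pH 3.66, and the third culture (*E. gallinarum*) is the factor most
positively correlated with pH — the tornado-chart signature that led
to its exclusion from the final starter blend.

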