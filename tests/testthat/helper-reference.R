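# Literal reference values for spot-checking the bundled datasets and the
# frozen fitted parameters used across the suite.  The spot dictionary is
# intentionally typed out cell-by-cell, independent of the fixture code.

ref_times <- seq(0, 36, by = 3)

ref_spot_timecourse <- list(
  # (variable, time_h, mean, sd)
  list("ph",            0, 6.37, 0.15),
  list("ph",           12, 4.68, 0.09),
  list("ph",           18, 4.06, 0.06),
  list("ph",           36, 3.77, 0.01),
  list("tta_pct",       0, 0.12, 0.01),
  list("tta_pct",      36, 0.53, 0.03),
  list("glucose_pct",   0, 0.55, 0.10),
  list("glucose_pct",  33, 2.12, 0.09),
  list("lab_log10cfu", 15, 8.10, 1.01),
  list("lab_log10cfu", 36, 7.68, 0.60),
  list("tvc_log10cfu",  0, 6.98, 0.05),
  list("tvc_log10cfu", 30, 7.29, 0.27)
)

ref_spot_design <- list(
  # (x1, x2, x3, response, mean, sd)
  list(0.050, 0.050, 0.050, "ph",             3.58, 0.15),
  list(0.100, 0.050, 0.100, "ph",             3.76, 0.11),
  list(0.050, 0.050, 0.100, "tta_pct",        0.61, 0.09),
  list(0.075, 0.075, 0.075, "viscosity_mpas", 6.71, 1.71),
  list(0.100, 0.100, 0.100, "viscosity_mpas", 10.67, 0.81)
)

# frozen least-squares results on the bundled time-course means, computed
# independently with stats::nls (port oracle) / stats::lm before the
# package fitters existed
ref_ph_fit  <- c(a = 3.3823393, b = -3.1878860, c = 0.0705232)
ref_ph_r2   <- 0.9714389
ref_tta_fit <- c(a = 0.6629679, b = 0.5749316, c = 0.0422761)
ref_tta_r2  <- 0.9812888
ref_glu_r2  <- 0.9471587

# published modified-Gompertz parameter set for the total viable count
ref_tvc_params <- c(K = 6.911, A = 0.790, mu_max = 0.202, lag = 0.000)

expand_replicates <- function(time, y, n = 3)
  list(t = rep(time, each = n), y = rep(y, each = n))
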