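#' Bundled reference datasets
#'
#' Two reference datasets from a published spontaneous pearl-millet
#' fermentation study ship with the package, reconstructed from the printed
#' summary tables (per-time or per-run mean and standard deviation of
#' triplicate readings, n = 3 throughout):
#'
#' * `"slurry_timecourse"`: a 36 h natural fermentation of pearl millet
#'   slurry at 37 degC sampled every 3 h (13 time points) for pH,
#'   titratable acidity (% lactic acid), glucose (%), lactic acid bacteria
#'   and total viable count (log10 CFU/mL). Returned as a
#'   [ferm_timeseries].
#' * `"starter_design"`: a 2^3 + centre factorial experiment inoculating
#'   pearl millet extract with three starter cultures (*Leuconostoc
#'   mesenteroides*, *Pediococcus pentosaceus*, *Enterococcus gallinarum*)
#'   at 0.05/0.10% (centre 0.075%) and measuring pH, titratable acidity and
#'   viscosity (mPa s) after 18 h. Returned as a [ferm_design].
#'
#' The LAB count at 15 h is printed to one decimal (8.1); the stored value
#' 8.10 assumes a trailing zero. The same tables are installed as plain CSV
#' under `system.file("extdata", package = "fermkin")`.
#'
#' @param name `"slurry_timecourse"` or `"starter_design"`.
#' @return A [ferm_timeseries] or [ferm_design].
#' @examples
#' ferm_fixture("slurry_timecourse")
#' @export
ferm_fixture <- function(name) {
  switch(match.arg(name, c("slurry_timecourse", "starter_design")),
         slurry_timecourse = slurry_timecourse_data(),
         starter_design = starter_design_data())
}

slurry_timecourse_data <- function() {
  df <- data.frame(
    time_h            = seq(0, 36, by = 3),
    ph_mean           = c(6.37, 6.09, 5.59, 5.41, 4.68, 4.36, 4.06, 3.96,
                          3.90, 3.84, 3.81, 3.78, 3.77),
    ph_sd             = c(0.15, 0.13, 0.09, 0.07, 0.09, 0.17, 0.06, 0.03,
                          0.05, 0.06, 0.04, 0.03, 0.01),
    tta_pct_mean      = c(0.12, 0.14, 0.18, 0.26, 0.31, 0.37, 0.42, 0.45,
                          0.45, 0.49, 0.48, 0.52, 0.53),
    tta_pct_sd        = c(0.01, 0.04, 0.01, 0.03, 0.01, 0.03, 0.01, 0.01,
                          0.03, 0.02, 0.02, 0.02, 0.03),
    glucose_pct_mean  = c(0.55, 0.80, 1.12, 1.57, 1.62, 1.92, 1.89, 1.77,
                          2.03, 1.91, 2.01, 2.12, 2.05),
    glucose_pct_sd    = c(0.10, 0.07, 0.10, 0.07, 0.03, 0.05, 0.03, 0.06,
                          0.03, 0.05, 0.02, 0.09, 0.03),
    lab_log10cfu_mean = c(7.04, 6.73, 7.74, 6.76, 7.87, 8.10, 7.79, 8.00,
                          7.99, 8.01, 7.97, 7.92, 7.68),
    lab_log10cfu_sd   = c(0.95, 0.46, 0.47, 0.02, 0.34, 1.01, 0.25, 0.56,
                          0.40, 0.28, 0.43, 1.24, 0.60),
    tvc_log10cfu_mean = c(6.98, 7.38, 7.92, 7.84, 7.89, 7.51, 7.80, 7.72,
                          7.78, 7.82, 7.29, 7.37, 7.81),
    tvc_log10cfu_sd   = c(0.05, 0.40, 0.14, 0.34, 0.19, 0.04, 0.26, 0.19,
                          0.16, 0.08, 0.27, 0.24, 0.17)
  )
  for (v in c("ph", "tta_pct", "glucose_pct", "lab_log10cfu", "tvc_log10cfu"))
    df[[paste0(v, "_n")]] <- 3L
  ferm_timeseries(df, batch_label = "pearl millet slurry, 37 degC")
}

starter_design_data <- function() {
  df <- data.frame(
    x1 = c(0.050, 0.050, 0.050, 0.050, 0.075, 0.100, 0.100, 0.100, 0.100),
    x2 = c(0.050, 0.050, 0.100, 0.100, 0.075, 0.050, 0.050, 0.100, 0.100),
    x3 = c(0.050, 0.100, 0.050, 0.100, 0.075, 0.050, 0.100, 0.050, 0.100),
    ph_mean             = c(3.58, 3.57, 3.63, 3.63, 3.57, 3.61, 3.76, 3.52, 3.64),
    ph_sd               = c(0.15, 0.16, 0.18, 0.20, 0.16, 0.17, 0.11, 0.14, 0.20),
    tta_pct_mean        = c(0.59, 0.61, 0.59, 0.56, 0.59, 0.55, 0.54, 0.61, 0.59),
    tta_pct_sd          = c(0.06, 0.09, 0.08, 0.02, 0.04, 0.03, 0.03, 0.02, 0.06),
    viscosity_mpas_mean = c(6.68, 1.32, 6.48, 5.72, 6.71, 2.11, 5.17, 4.62, 10.67),
    viscosity_mpas_sd   = c(4.42, 1.76, 4.01, 5.96, 1.71, 0.84, 3.98, 4.84, 0.81)
  )
  for (r in c("ph", "tta_pct", "viscosity_mpas"))
    df[[paste0(r, "_n")]] <- 3L
  ferm_design(df, factor_names = c("L. mesenteroides", "P. pentosaceus",
                                   "E. gallinarum"))
}

#' Reference fitted parameter sets
#'
#' Published parameter estimates for the bundled slurry time course, useful
#' as generator truth or as baseline parameter sets: exponential
#' acidification parameters `(a, b, c)` for pH and titratable acidity,
#' quadratic glucose coefficients `(c0, c1, c2)`, and modified-Gompertz
#' parameters `(K, A, mu_max, lag)` for the total viable count. The
#' published lactic-acid-bacteria Gompertz row carries a typographic error
#' in its rise `A` (0.092, while the data rise by about 1 log); the value
#' returned here (`A = 0.981`) is the least-squares refit on the bundled
#' means, which matches the published `K`, `mu_max` and `lag` to print
#' precision.
#'
#' @return A named list of named numeric vectors.
#' @examples
#' ferm_reference_params()$ph
#' @export
ferm_reference_params <- function() {
  list(
    ph          = c(a = 3.382, b = -3.188, c = 0.071),
    tta_pct     = c(a = 0.663, b = 0.575, c = 0.042),
    glucose_pct = c(c0 = 0.584, c1 = 0.107, c2 = -0.002),
    lab_log10cfu = c(K = 6.971, A = 0.981, mu_max = 0.092, lag = 3.903),
    tvc_log10cfu = c(K = 6.911, A = 0.790, mu_max = 0.202, lag = 0.000)
  )
}
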