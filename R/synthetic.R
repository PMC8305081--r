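#' Simulate a replicated fermentation time course
#'
#' Forward-simulates the fermentation models with Gaussian replicate noise
#' and tabulates per-time mean/sd/n, emulating the structure of a bench
#' time course (13 samplings at 3 h intervals over 36 h, triplicate
#' readings). Truth defaults to the reference parameter sets of the
#' bundled slurry dataset ([ferm_reference_params()]). Noise is
#' homoscedastic per variable by default; a per-time vector of standard
#' deviations is accepted for stress tests.
#'
#' @param times sampling times (hours), strictly increasing.
#' @param exponential named list of `c(a, b, c)` truths per acid variable.
#' @param quadratic named list of `c(c0, c1, c2)` truths per sugar
#'   variable.
#' @param gompertz named list of `c(K, A, mu_max, lag)` truths per count
#'   variable.
#' @param noise_sd named vector (or list of per-time vectors) of replicate
#'   standard deviations, one entry per simulated variable; defaults to
#'   magnitudes typical of the bundled dataset.
#' @param n_replicates replicates per time point.
#' @param seed integer seed; identical seeds give identical tables.
#' @param keep_replicates attach the raw replicate draws as attribute
#'   `"replicates"` (a named list of time-by-replicate matrices).
#' @param batch_label label for the simulated batch.
#' @return A [ferm_timeseries].
#' @examples
#' ts <- synth_timeseries(seed = 1, noise_sd = c(ph = 0))
#' @export
synth_timeseries <- function(times = seq(0, 36, by = 3),
                             exponential = ferm_reference_params()[c("ph", "tta_pct")],
                             quadratic = ferm_reference_params()["glucose_pct"],
                             gompertz = ferm_reference_params()[c("lab_log10cfu", "tvc_log10cfu")],
                             noise_sd = c(ph = 0.09, tta_pct = 0.02,
                                          glucose_pct = 0.06,
                                          lab_log10cfu = 0.5,
                                          tvc_log10cfu = 0.2),
                             n_replicates = 3, seed = NULL,
                             keep_replicates = FALSE,
                             batch_label = "synthetic") {
  if (any(diff(times)  <= 0))
    stop("sampling times must be strictly increasing", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  curves <- list()
  for (v in names(exponential)) {
    p <- exponential[[v]]
    curves[[v]] <- eval_exponential(p[["a"]], p[["b"]], p[["c"]], times)
  }
  for (v in names(quadratic)) {
    p <- quadratic[[v]]
    curves[[v]] <- p[[1]] + p[[2]] * times + p[[3]] * times^2
  }
  for (v in names(gompertz)) {
    p <- gompertz[[v]]
    curves[[v]] <- eval_gompertz(times, p[["K"]], p[["A"]], p[["mu_max"]],
                                 p[["lag"]])
  }
  if (is.null(names(noise_sd)))
    stop("noise_sd must be named by variable", call. = FALSE)
  df <- data.frame(time_h = times)
  reps <- list()
  for (v in names(curves)) {
    s <- if (v %in% names(noise_sd)) noise_sd[[v]] else 0
    if (any(s < 0)) stop("noise_sd must be non-negative", call. = FALSE)
    s <- rep_len(s, length(times))
    draw <- matrix(rnorm(length(times) * n_replicates,
                         mean = rep(curves[[v]], n_replicates),
                         sd = rep(s, n_replicates)),
                   nrow = length(times))
    df[[paste0(v, "_mean")]] <- rowMeans(draw)
    df[[paste0(v, "_sd")]] <- if (n_replicates > 1) apply(draw, 1, sd)
                              else rep(0, length(times))
    df[[paste0(v, "_n")]] <- n_replicates
    reps[[v]] <- draw
  }
  out <- ferm_timeseries(df, batch_label = batch_label)
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' Simulate a replicated factorial starter-culture experiment
#'
#' Forward-simulates the factorial response model at the given design
#' points with Gaussian replicate noise and tabulates per-run mean/sd/n.
#' Defaults emulate the reference experiment: the 2^3 corners at
#' 0.05/0.10% plus the centre 0.075%, true coefficients taken from the
#' published response models, and residual standard deviations equal to
#' the square root of each model's dispersion scale.
#'
#' @param levels data frame or matrix of inoculum triples (columns
#'   `x1`, `x2`, `x3`).
#' @param coefficients named list of named coefficient vectors per
#'   response (terms as in [factorial_coefficients()]).
#' @param three_way named logical: which responses carry the three-way
#'   term.
#' @param residual_sd named vector of replicate standard deviations.
#' @param n_replicates replicates per design point.
#' @param seed integer seed.
#' @param keep_replicates attach raw replicate draws as attribute
#'   `"replicates"`.
#' @return A [ferm_design].
#' @examples
#' d <- synth_design(seed = 1)
#' fit_factorial(d, "tta_pct")
#' @export
synth_design <- function(levels = default_design_points(),
                         coefficients = ferm_reference_glm(),
                         three_way = c(ph = FALSE, tta_pct = FALSE,
                                       viscosity_mpas = TRUE),
                         residual_sd = c(ph = sqrt(0.027),
                                         tta_pct = sqrt(0.003),
                                         viscosity_mpas = sqrt(12.49)),
                         n_replicates = 3, seed = NULL,
                         keep_replicates = FALSE) {
  levels <- as.data.frame(levels)
  names(levels)[1:3] <- c("x1", "x2", "x3")
  if (any(residual_sd < 0))
    stop("residual_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  df <- levels[c("x1", "x2", "x3")]
  reps <- list()
  for (r in names(coefficients)) {
    tw <- isTRUE(three_way[[r]])
    m <- factorial_coefficients(coefficients[[r]], three_way = tw)
    mu <- predict(m, levels)
    s <- if (r %in% names(residual_sd)) residual_sd[[r]] else 0
    draw <- matrix(rnorm(length(mu) * n_replicates,
                         mean = rep(mu, n_replicates), sd = s),
                   nrow = length(mu))
    df[[paste0(r, "_mean")]] <- rowMeans(draw)
    df[[paste0(r, "_sd")]] <- if (n_replicates > 1) apply(draw, 1, sd)
                              else rep(0, length(mu))
    df[[paste0(r, "_n")]] <- n_replicates
    reps[[r]] <- draw
  }
  if ("viscosity_mpas_mean" %in% names(df)) {
    neg <- df$viscosity_mpas_mean < 0
    df$viscosity_mpas_mean[neg] <- 0   # viscosity cannot be negative
  }
  out <- ferm_design(df)
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}

#' @rdname synth_design
#' @export
default_design_points <- function() {
  corners <- expand.grid(x1 = c(0.05, 0.10), x2 = c(0.05, 0.10),
                         x3 = c(0.05, 0.10))
  rbind(corners, data.frame(x1 = 0.075, x2 = 0.075, x3 = 0.075))
}

#' Reference factorial response coefficients
#'
#' Published coefficient sets of the three response models fitted to the
#' bundled starter-culture experiment: pH and titratable acidity with the
#' six-term model (intercept, mains, two-way interactions), viscosity with
#' the additional three-way product. Used as generator truth by
#' [synth_design()] and for propagating published models without
#' refitting.
#'
#' @return Named list of named coefficient vectors.
#' @export
ferm_reference_glm <- function() {
  list(
    ph = c(`(Intercept)` = 3.44, x1 = 1.28, x2 = 4.41, x3 = -2.73,
           `x1:x2` = -63.00, `x1:x3` = 55.00, `x2:x3` = -2.33),
    tta_pct = c(`(Intercept)` = 0.686, x1 = -2.383, x2 = -1.15, x3 = 1.05,
                `x1:x2` = 32, `x1:x3` = -4.667, `x2:x3` = -12.667),
    viscosity_mpas = c(`(Intercept)` = 34.44, x1 = -347.18, x2 = -183.45,
                       x3 = -400.45, `x1:x2` = 1742.13, `x1:x3` = 4020.87,
                       `x2:x3` = 2494.20, `x1:x2:x3` = -13017.33)
  )
}
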