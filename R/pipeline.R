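#' Pearson correlation matrix of fermentation variables
#'
#' Pairwise Pearson correlations of the per-time means of the chosen
#' variables, with qualitative strength labels by the conventional |r|
#' bands: very weak < 0.2, weak < 0.4, moderate < 0.6, strong < 0.8,
#' very strong >= 0.8.
#'
#' @param x a [ferm_timeseries] with at least 3 time points.
#' @param variables variables to correlate (default: all present).
#' @return An object of class `ferm_cor` with components `r` (symmetric
#'   correlation matrix, unit diagonal) and `label` (matrix of strength
#'   descriptions such as `"very strong, negative"`).
#' @examples
#' pearson_matrix(ferm_fixture("slurry_timecourse"), c("ph", "tta_pct"))
#' @export
pearson_matrix <- function(x, variables = ts_variables(x)) {
  if (nrow(x) < 3) stop("need at least 3 shared time points", call. = FALSE)
  M <- sapply(variables, function(v) ts_means(x, v))
  sds <- apply(M, 2, sd)
  if (any(sds == 0))
    stop(sprintf("degenerate variance in variable(s): %s",
                 paste(variables[sds == 0], collapse = ", ")), call. = FALSE)
  r <- cor(M, method = "pearson")
  lab <- matrix(correlation_label(r), nrow = nrow(r), dimnames = dimnames(r))
  structure(list(r = r, label = lab), class = "ferm_cor")
}

correlation_label <- function(r) {
  a <- abs(r)
  strength <- ifelse(a < 0.2, "very weak",
              ifelse(a < 0.4, "weak",
              ifelse(a < 0.6, "moderate",
              ifelse(a < 0.8, "strong", "very strong"))))
  paste0(strength, ", ", ifelse(r < 0, "negative", "positive"))
}

#' @export
print.ferm_cor <- function(x, digits = 3, ...) {
  cat("Pearson correlation of time-point means\n")
  print(round(x$r, digits))
  invisible(x)
}

#' Run the full fermentation analysis pipeline
#'
#' Chains the stages on a fermentation time course and a factorial
#' starter-culture design: exponential acidification fits (pH, titratable
#' acidity), the quadratic sugar fit, modified-Gompertz growth fits,
#' plateau detection for the acid variables, the correlation matrix,
#' per-response factorial models, and Monte Carlo propagation per
#' response. The run is deterministic given `seed` (each response's Monte
#' Carlo draws use `seed + k` for a stable small offset `k`).
#'
#' @param timeseries a [ferm_timeseries] or path to its CSV.
#' @param design a [ferm_design] or path to its CSV.
#' @param alpha significance level for [plateau_time()].
#' @param mc_n Monte Carlo cases per response.
#' @param mc_ranges per-factor sampling ranges.
#' @param three_way_responses responses fitted with the three-way term.
#' @param seed integer seed for the Monte Carlo stage.
#' @param on_means fit kinetic models on per-time means (the default; the
#'   alternative expands each time point into `n` pseudo-replicates at the
#'   mean, which leaves point estimates unchanged for balanced data).
#' @return An object of class `ferm_report`: a list with sections
#'   `kinetics`, `growth`, `plateau`, `correlations`, `glm`,
#'   `monte_carlo` and `meta` (package version, seed, input checksums
#'   when paths were given).
#' @examples
#' rep <- run_all(ferm_fixture("slurry_timecourse"),
#'                ferm_fixture("starter_design"), mc_n = 200, seed = 1)
#' @export
run_all <- function(timeseries, design, alpha = 0.05, mc_n = 1000,
                    mc_ranges = default_mc_ranges(),
                    three_way_responses = "viscosity_mpas", seed = 1,
                    on_means = TRUE) {
  checksums <- list()
  if (is.character(timeseries)) {
    checksums$timeseries <- unname(tools::md5sum(timeseries))
    timeseries <- read_timeseries_csv(timeseries)
  }
  if (is.character(design)) {
    checksums$design <- unname(tools::md5sum(design))
    design <- read_design_csv(design)
  }
  tvars <- ts_variables(timeseries)
  tt <- timeseries$time_h
  get_y <- function(v) {
    if (on_means) list(t = tt, y = ts_means(timeseries, v))
    else {
      n <- ts_ns(timeseries, v)
      list(t = rep(tt, n), y = rep(ts_means(timeseries, v), n))
    }
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  kinetics <- list()
  for (v in intersect(c("ph", "tta_pct"), tvars)) {
    d <- get_y(v)
    kinetics[[v]] <- stage(paste0("kinetics/", v), fit_exponential(d$t, d$y))
  }
  for (v in intersect("glucose_pct", tvars)) {
    d <- get_y(v)
    kinetics[[v]] <- stage(paste0("kinetics/", v), fit_quadratic(d$t, d$y))
  }

  growth <- list()
  for (v in intersect(c("lab_log10cfu", "tvc_log10cfu"), tvars)) {
    d <- get_y(v)
    growth[[v]] <- stage(paste0("growth/", v), fit_gompertz(d$t, d$y))
  }

  plateau <- list()
  for (v in intersect(c("ph", "tta_pct"), tvars))
    plateau[[v]] <- stage(paste0("plateau/", v),
                          plateau_time(timeseries, v, alpha = alpha))

  correlations <- stage("correlations", pearson_matrix(timeseries, tvars))

  glm <- list(); mc <- list()
  for (k in seq_along(design_responses(design))) {
    r <- design_responses(design)[k]
    tw <- r %in% three_way_responses
    glm[[r]] <- stage(paste0("glm/", r),
                      fit_factorial(design, r, three_way = tw))
    mc[[r]] <- stage(paste0("mc/", r),
                     monte_carlo(glm[[r]], n = mc_n, ranges = mc_ranges,
                                 seed = seed + k))
  }

  structure(list(
    kinetics = kinetics, growth = growth, plateau = plateau,
    correlations = correlations, glm = glm, monte_carlo = mc,
    meta = list(package_version = as.character(packageVersion("fermkin")),
                seed = seed, alpha = alpha, mc_n = mc_n,
                on_means = on_means, checksums = checksums)
  ), class = "ferm_report")
}

#' @export
print.ferm_report <- function(x, ...) {
  cat("Fermentation analysis report\n")
  for (v in names(x$kinetics)) {
    f <- x$kinetics[[v]]
    cat(sprintf("  %s: %s, R2 = %.3f\n", v,
                paste(sprintf("%s=%.3f", names(coef(f)), coef(f)),
                      collapse = " "), f$r2))
  }
  for (v in names(x$growth)) {
    f <- x$growth[[v]]
    cat(sprintf("  %s: %s, E%% = %.2f\n", v,
                paste(sprintf("%s=%.3f", names(coef(f)), coef(f)),
                      collapse = " "), f$e_pct))
  }
  for (v in names(x$plateau))
    cat(sprintf("  plateau %s: %g h\n", v, x$plateau[[v]]))
  for (r in names(x$monte_carlo))
    cat(sprintf("  MC %s: p95 = %.3f\n", r, x$monte_carlo[[r]]$percentiles[["p95"]]))
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Writes a machine-readable report. Reruns of [run_all()] with identical
#' inputs and seed serialise to byte-identical JSON.
#'
#' @param report a `ferm_report`.
#' @param path output file; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_report_json <- function(report, path = NULL) {
  strip <- function(x) {
    if (inherits(x, "ferm_exp") || inherits(x, "ferm_quad"))
      return(list(coefficients = as.list(coef(x)), r2 = x$r2,
                  n_points = x$n_points,
                  residuals = as.numeric(x$residuals)))
    if (inherits(x, "ferm_gompertz"))
      return(list(coefficients = as.list(coef(x)), e_pct = x$e_pct,
                  n_points = x$n_points,
                  residuals = as.numeric(x$residuals)))
    if (inherits(x, "ferm_glm"))
      return(list(coefficients = x$coefficients, scale = x$scale,
                  n_obs = x$n_obs, dof_residual = x$dof_residual,
                  three_way = x$three_way))
    if (inherits(x, "ferm_mc"))
      return(list(n_cases = x$n_cases, seed = x$seed,
                  percentiles = as.list(x$percentiles),
                  sensitivity = as.list(x$sensitivity),
                  contribution_pct = as.list(x$contribution_pct)))
    if (inherits(x, "ferm_cor"))
      return(list(r = x$r, label = x$label))
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  payload <- lapply(unclass(report), strip)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}
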