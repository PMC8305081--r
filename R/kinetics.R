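#' Exponential acidification model
#'
#' The primary acidification model `y(t) = a - b * exp(-c * t)`, where `a`
#' is the horizontal asymptote in response units, `b = a - y(0)` (negative
#' when the response decreases towards the asymptote from above, as pH
#' does; positive when it rises towards it, as titratable acidity does) and
#' `c` is the rate constant in 1/h.
#'
#' @param a horizontal asymptote (response units).
#' @param b `a` minus the intercept (response units; may be negative).
#' @param c rate constant (1/h), positive for a kinetic fit.
#' @param t time (hours); vectorised.
#' @return Model value(s) at `t`.
#' @examples
#' eval_exponential(3.382, -3.188, 0.071, 0)   # initial pH, about 6.57
#' @export
eval_exponential <- function(a, b, c, t) a - b * exp(-c * t)

#' Fit the exponential acidification model
#'
#' Least-squares fit of `y = a - b*exp(-c*t)` by Levenberg-Marquardt with
#' multi-start restarts. The default start takes `a` at the last observed
#' value, `b = a - y(first)` and `c = 0.1` 1/h; restarts jitter the rate
#' start. The coefficient of determination is computed as
#' 1 - RSS/CSS over the fitted points (see [r_squared()]) and standard
#' errors come from the local linearisation at the optimum.
#'
#' @param time sampling times (hours), strictly increasing, length >= 4.
#' @param y response values (same length).
#' @param weights optional per-point least-squares weights.
#' @param init optional named start vector `c(a=, b=, c=)`.
#' @param max_restarts number of jittered restarts tried after the default
#'   start fails or to escape a poor local optimum.
#' @return An object of class `ferm_exp` with components `coefficients`
#'   (a, b, c), `se`, `r2`, `n_points`, `converged`, `residuals`, `fitted`,
#'   `rss` and the input data; it supports `coef()`, `predict()`,
#'   `residuals()`, `fitted()`, `summary()` and `print()`.
#' @examples
#' ts <- ferm_fixture("slurry_timecourse")
#' fit <- fit_exponential(ts$time_h, ts_means(ts, "ph"))
#' coef(fit)["c"]     # acidification rate, about 0.071 1/h
#' @export
fit_exponential <- function(time, y, weights = NULL, init = NULL,
                            max_restarts = 20) {
  check_times(time, y, min_points = 4)
  if (is.null(init)) {
    a0 <- y[length(y)]
    init <- c(a = a0, b = a0 - y[1], c = 0.1)
  }
  fml <- y ~ a - b * exp(-c * t)
  dat <- list(t = time, y = y)
  best <- nls_multistart(fml, dat, init, weights = weights,
                         jitter_par = "c", max_restarts = max_restarts,
                         lower = c(a = -Inf, b = -Inf, c = 1e-8))
  est <- coef(best$fit)
  pred <- eval_exponential(est["a"], est["b"], est["c"], time)
  structure(list(
    coefficients = est,
    se = best$se,
    r2 = r_squared(y, pred),
    n_points = length(y),
    converged = best$converged,
    residuals = y - pred,
    fitted = pred,
    rss = sum((y - pred)^2 * (if (is.null(weights)) 1 else weights)),
    data = data.frame(time = time, y = y)
  ), class = "ferm_exp")
}

#' @export
coef.ferm_exp <- function(object, ...) object$coefficients

#' @export
fitted.ferm_exp <- function(object, ...) object$fitted

#' @export
residuals.ferm_exp <- function(object, ...) object$residuals

#' @export
predict.ferm_exp <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
       else if (is.list(newdata)) newdata$time else newdata
  p <- object$coefficients
  eval_exponential(p["a"], p["b"], p["c"], t)
}

#' @export
print.ferm_exp <- function(x, digits = 4, ...) {
  cat("Exponential acidification fit: y = a - b*exp(-c*t)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("R2 = %.*f on %d points%s\n", digits, x$r2, x$n_points,
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
summary.ferm_exp <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, std_error = object$se)
  structure(list(coefficients = tab, r2 = object$r2,
                 n_points = object$n_points, converged = object$converged,
                 rss = object$rss),
            class = "summary.ferm_exp")
}

#' @export
print.summary.ferm_exp <- function(x, ...) {
  cat("Exponential acidification fit\n")
  print(x$coefficients)
  cat(sprintf("RSS = %.6g, R2 = %.4f, n = %d\n", x$rss, x$r2, x$n_points))
  invisible(x)
}

#' Fit the quadratic sugar model
#'
#' Ordinary least squares fit of `y = c0 + c1*t + c2*t^2`, the empirical
#' model for soluble sugar (glucose) during fermentation: amylolytic
#' release of glucose dominates early, consumption flattens and reverses
#' the trend late.
#'
#' @param time sampling times (hours), length >= 3.
#' @param y response values.
#' @return An object of class `ferm_quad` with `coefficients`
#'   (c0, c1, c2), `r2`, `n_points`, `residuals`, `fitted`; supports
#'   `coef()`, `predict()`, `print()`.
#' @examples
#' ts <- ferm_fixture("slurry_timecourse")
#' fit_quadratic(ts$time_h, ts_means(ts, "glucose_pct"))
#' @export
fit_quadratic <- function(time, y) {
  if (length(time) != length(y)) stop("time and y differ in length", call. = FALSE)
  if (length(y) < 3) stop("quadratic fit needs at least 3 points", call. = FALSE)
  X <- cbind(1, time, time^2)
  if (qr(X)$rank < 3)
    stop("singular normal equations: time values do not span a quadratic",
         call. = FALSE)
  fit <- lm(y ~ time + I(time^2))
  est <- setNames(coef(fit), c("c0", "c1", "c2"))
  pred <- as.numeric(fitted(fit))
  structure(list(coefficients = est, r2 = r_squared(y, pred),
                 n_points = length(y), residuals = y - pred, fitted = pred,
                 data = data.frame(time = time, y = y)),
            class = "ferm_quad")
}

#' @export
coef.ferm_quad <- function(object, ...) object$coefficients

#' @export
predict.ferm_quad <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
       else if (is.list(newdata)) newdata$time else newdata
  p <- object$coefficients
  p["c0"] + p["c1"] * t + p["c2"] * t^2
}

#' @export
print.ferm_quad <- function(x, digits = 4, ...) {
  cat("Quadratic kinetics fit: y = c0 + c1*t + c2*t^2\n")
  print(round(x$coefficients, digits))
  cat(sprintf("R2 = %.*f on %d points\n", digits, x$r2, x$n_points))
  invisible(x)
}

#' Coefficient of determination
#'
#' `R2 = 1 - RSS/CSS`: one minus the residual sum of squares over the
#' corrected (about-the-mean) sum of squares of the observations. May be
#' negative for models worse than the mean.
#'
#' @param observed observed values (not all identical).
#' @param predicted model predictions, same length.
#' @return R-squared as a fraction (multiply by 100 for %).
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))   # 0.5
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length", call. = FALSE)
  if (length(observed) < 2)
    stop("R2 needs at least 2 points", call. = FALSE)
  css <- sum((observed - mean(observed))^2)
  if (css == 0)
    stop("degenerate variance: observations are all identical", call. = FALSE)
  1 - sum((observed - predicted)^2) / css
}

#' Titratable acidity from an NaOH titration
#'
#' Converts a titration reading to total titratable acidity expressed as
#' % lactic acid:
#' `TTA = naoh_ml * naoh_molarity * lactic_equivalent_mg /
#'        (sample_ml * 1000) * 100`,
#' with 0.1 M NaOH equivalent to 90.08 mg lactic acid.
#'
#' @param naoh_ml titrant volume (mL), >= 0; vectorised.
#' @param naoh_molarity molarity of the NaOH titrant.
#' @param sample_ml sample volume (mL), > 0.
#' @param lactic_equivalent_mg milligram equivalent factor of lactic acid.
#' @return Titratable acidity in % lactic acid.
#' @examples
#' tta_percent(1.33, 0.1, 10)   # about 0.12 %
#' @export
tta_percent <- function(naoh_ml, naoh_molarity = 0.1, sample_ml = 10,
                        lactic_equivalent_mg = 90.08) {
  if (any(sample_ml <= 0)) stop("sample volume must be positive", call. = FALSE)
  if (any(naoh_molarity <= 0) || any(lactic_equivalent_mg <= 0))
    stop("molarity and equivalent factor must be positive", call. = FALSE)
  if (any(naoh_ml < 0)) stop("titrant volume must be non-negative", call. = FALSE)
  naoh_ml * naoh_molarity * lactic_equivalent_mg / (sample_ml * 1000) * 100
}

#' Plateau (stabilisation) time of a fermentation variable
#'
#' Finds the earliest sampling time from which the variable no longer
#' changes between consecutive sampling points: every later consecutive
#' pair must fail a two-sample Welch comparison (statistic reconstructed
#' from per-time mean, sd and replicate count) at level `alpha`. Returns
#' the last sampling time if the series never stabilises. This is a
#' summary-statistics surrogate for the multiple-range tests used on raw
#' replicates at the bench, and identifies the optimum fermentation time
#' region.
#'
#' @param x a [ferm_timeseries].
#' @param variable variable name, e.g. `"ph"`.
#' @param alpha significance level for the pairwise comparisons.
#' @return The plateau time in hours.
#' @examples
#' plateau_time(ferm_fixture("slurry_timecourse"), "ph")
#' @export
plateau_time <- function(x, variable, alpha = 0.05) {
  t <- x$time_h
  m <- ts_means(x, variable)
  s <- ts_sds(x, variable)
  n <- ts_ns(x, variable)
  if (anyNA(s) || anyNA(n))
    stop("insufficient replication: sd and n required at every time point",
         call. = FALSE)
  k <- length(t)
  if (k < 2) return(t[1])
  p <- vapply(seq_len(k - 1), function(i)
    welch_p(m[i], s[i], n[i], m[i + 1], s[i + 1], n[i + 1]), numeric(1))
  for (i in seq_len(k - 1))
    if (all(p[i:(k - 1)] > alpha)) return(t[i])
  t[k]
}

# two-sided Welch p-value from summary statistics
welch_p <- function(m1, s1, n1, m2, s2, n2) {
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (v1 + v2 == 0) return(if (m1 == m2) 1 else 0)
  tt <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  2 * pt(-abs(tt), df)
}

check_times <- function(time, y, min_points) {
  if (length(time) != length(y))
    stop("time and y differ in length", call. = FALSE)
  if (length(y) < min_points)
    stop(sprintf("fit needs at least %d points", min_points), call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
}

# multi-start Levenberg-Marquardt wrapper; returns best fit by RSS together
# with linearisation standard errors and a convergence flag.  On total
# failure raises a condition carrying the best iterate seen.
nls_multistart <- function(formula, data, init, weights = NULL,
                           jitter_par, max_restarts = 20, lower = NULL,
                           upper = NULL, seed_offset = 17) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-8, maxiter = 500)
  starts <- list(as.list(init))
  # deterministic jitter ladder around the nominal rate start
  fac <- c(0.25, 0.5, 0.75, 1.5, 2, 3, 5, 8, 0.1, 10, 0.05, 15, 0.02, 20,
           0.3, 4, 6, 0.15, 12, 25)
  for (i in seq_len(min(max_restarts, length(fac)))) {
    s <- as.list(init)
    s[[jitter_par]] <- init[[jitter_par]] * fac[i]
    starts[[length(starts) + 1]] <- s
  }
  best <- NULL
  best_rss <- Inf
  last_err <- NULL
  for (s in starts) {
    args <- list(formula, data = data, start = s, lower = lower,
                 upper = upper, control = ctrl)
    if (!is.null(weights)) args$weights <- weights
    fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)
    if (inherits(fit, "error")) { last_err <- fit; next }
    rss <- sum(resid(fit)^2)
    if (rss < best_rss - 1e-12) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) {
    cond <- structure(class = c("ferm_nonconvergence", "error", "condition"),
                      list(message = paste0("nonlinear fit failed to converge: ",
                                            conditionMessage(last_err)),
                           call = sys.call(-1), best_iterate = init))
    stop(cond)
  }
  sm <- summary(best)
  list(fit = best,
       se = setNames(sm$coefficients[, "Std. Error"],
                     rownames(sm$coefficients)),
       converged = isTRUE(best$convInfo$isConv))
}
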