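#' Modified Gompertz growth model
#'
#' The reparameterised (Zwietering-type) Gompertz curve on the log10
#' CFU/mL scale:
#' `log10 N(t) = K + A * exp(-exp(mu_max * e * (lag - t) / A + 1))`,
#' where `K` is the initial level (log10 CFU/mL), `A` the rise from the
#' initial level to the stationary-phase density (log10 CFU/mL), `mu_max`
#' the maximum growth rate (delta log10 CFU/mL per hour) and `lag` the lag
#' time in hours. The curve is non-decreasing in `t`, equals
#' `K + A*exp(-e)` at `t = lag`, and tends to `K + A` as `t` grows.
#'
#' @param t time (hours); vectorised.
#' @param K initial level (log10 CFU/mL).
#' @param A rise to the stationary density (log10 CFU/mL), > 0.
#' @param mu_max maximum growth rate (log10 CFU/mL per h), >= 0.
#' @param lag lag time (hours), >= 0.
#' @param degenerate_ok if `TRUE`, `A = 0` returns `K` with a warning
#'   instead of an error.
#' @return Predicted log10 CFU/mL.
#' @examples
#' eval_gompertz(0, K = 6.911, A = 0.790, mu_max = 0.202, lag = 0)
#' @export
eval_gompertz <- function(t, K, A, mu_max, lag = 0, degenerate_ok = FALSE) {
  if (A < 0 || mu_max < 0 || lag < 0)
    stop("A, mu_max and lag must be non-negative", call. = FALSE)
  if (A == 0) {
    if (!degenerate_ok)
      stop("degenerate model: A = 0 gives a flat curve at K", call. = FALSE)
    warning("A = 0: returning the initial level K")
    return(rep(K, length(t)))
  }
  K + A * exp(-exp(mu_max * exp(1) * (lag - t) / A + 1))
}

#' Mean relative deviation modulus (E%)
#'
#' `E% = (1/n) * sum(|O - P| / O) * 100`, the average relative percent
#' difference between experimental (`O`) and predicted (`P`) values; lower
#' is better, with E% below ~10% conventionally read as an adequate fit in
#' food-engineering practice.
#'
#' @param observed experimental values, all > 0.
#' @param predicted model predictions, same length.
#' @return E% in percent.
#' @examples
#' e_percent(c(10, 20), c(9, 22))   # 10
#' @export
e_percent <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length", call. = FALSE)
  if (length(observed) < 1) stop("empty input", call. = FALSE)
  if (any(observed <= 0))
    stop("E% is undefined for observations <= 0", call. = FALSE)
  mean(abs(observed - predicted) / observed) * 100
}

#' Fit the modified Gompertz growth model
#'
#' Least-squares fit of [eval_gompertz()] by Levenberg-Marquardt with
#' multi-start restarts, constrained to `A > 0`, `mu_max >= 0`,
#' `lag >= 0`. Default initialisation: `K` at the first observation, `A`
#' at the observed rise (max minus first), `mu_max` at the steepest
#' observed secant slope, and `lag` at the time of steepest slope minus
#' `A/mu_max`, clipped at zero. The mean relative deviation modulus of
#' the fit ([e_percent()]) is reported alongside the parameters.
#'
#' @param time sampling times (hours), strictly increasing, length >= 5.
#' @param log_counts observed counts on the log10 CFU/mL scale.
#' @param init optional named start vector `c(K=, A=, mu_max=, lag=)`.
#' @param max_restarts jittered restarts for the growth-rate start.
#' @return An object of class `ferm_gompertz` with `coefficients`
#'   (K, A, mu_max, lag), `se`, `e_pct`, `rss`, `n_points`, `converged`,
#'   `residuals`, `fitted`; supports `coef()`, `predict()`, `residuals()`,
#'   `fitted()`, `summary()` and `print()`.
#' @examples
#' ts <- ferm_fixture("slurry_timecourse")
#' fit_gompertz(ts$time_h, ts_means(ts, "tvc_log10cfu"))
#' @export
fit_gompertz <- function(time, log_counts, init = NULL, max_restarts = 20) {
  check_times(time, log_counts, min_points = 5)
  y <- log_counts
  if (max(y) <= y[1]) {
    # no observable rise: the model boundary (flat curve at the mean) is
    # the least-squares solution within the constraint set
    warning("monotone-decreasing counts: returning a boundary fit")
    est <- c(K = mean(y), A = 1e-6, mu_max = 0, lag = 0)
    pred <- rep(mean(y), length(y))
    return(structure(list(
      coefficients = est, se = c(K = NA, A = NA, mu_max = NA, lag = NA),
      e_pct = e_percent(y, pred), rss = sum((y - pred)^2),
      n_points = length(y), converged = FALSE, residuals = y - pred,
      fitted = pred, data = data.frame(time = time, y = y)
    ), class = "ferm_gompertz"))
  }
  if (is.null(init)) {
    slopes <- diff(y) / diff(time)
    i_max <- which.max(slopes)
    mu0 <- max(slopes[i_max], 1e-3)
    A0 <- max(max(y) - y[1], 0.1)
    lag0 <- max(time[i_max] - A0 / mu0, 0)
    init <- c(K = y[1], A = A0, mu_max = mu0, lag = lag0)
  }
  fml <- y ~ K + A * exp(-exp(mu_max * exp(1) * (lag - t) / A + 1))
  dat <- list(t = time, y = y)
  best <- nls_multistart(fml, dat, init, jitter_par = "mu_max",
                         max_restarts = max_restarts,
                         lower = c(K = -Inf, A = 1e-6, mu_max = 0, lag = 0))
  est <- coef(best$fit)
  pred <- eval_gompertz(time, est["K"], est["A"], est["mu_max"], est["lag"])
  structure(list(
    coefficients = est,
    se = best$se,
    e_pct = e_percent(y, pred),
    rss = sum((y - pred)^2),
    n_points = length(y),
    converged = best$converged,
    residuals = y - pred,
    fitted = pred,
    data = data.frame(time = time, y = y)
  ), class = "ferm_gompertz")
}

#' @export
coef.ferm_gompertz <- function(object, ...) object$coefficients

#' @export
fitted.ferm_gompertz <- function(object, ...) object$fitted

#' @export
residuals.ferm_gompertz <- function(object, ...) object$residuals

#' @export
predict.ferm_gompertz <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time
       else if (is.list(newdata)) newdata$time else newdata
  p <- object$coefficients
  eval_gompertz(t, p["K"], p["A"], p["mu_max"], p["lag"])
}

#' @export
print.ferm_gompertz <- function(x, digits = 4, ...) {
  cat("Modified Gompertz growth fit (log10 CFU/mL)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("E%% = %.3f, RSS = %.5g on %d points%s\n", x$e_pct, x$rss,
              x$n_points, if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}

#' @export
summary.ferm_gompertz <- function(object, ...) {
  tab <- data.frame(estimate = object$coefficients, std_error = object$se)
  structure(list(coefficients = tab, e_pct = object$e_pct, rss = object$rss,
                 n_points = object$n_points, converged = object$converged),
            class = "summary.ferm_gompertz")
}

#' @export
print.summary.ferm_gompertz <- function(x, ...) {
  cat("Modified Gompertz growth fit\n")
  print(x$coefficients)
  cat(sprintf("E%% = %.3f, RSS = %.5g, n = %d\n", x$e_pct, x$rss, x$n_points))
  invisible(x)
}
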