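#' Uniform inoculum sampling for Monte Carlo propagation
#'
#' Draws `n` i.i.d. uniform inoculum triples, one column per culture. The
#' default range per factor is the experimental range 0.05-0.10% w/w.
#'
#' @param n number of cases, >= 1.
#' @param ranges list of three `c(lo, hi)` pairs (or a 2 x 3 matrix).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return An `n` x 3 matrix with columns `x1`, `x2`, `x3`.
#' @examples
#' head(mc_sample_uniform(5, seed = 1))
#' @export
mc_sample_uniform <- function(n, ranges = default_mc_ranges(), seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (is.matrix(ranges)) ranges <- lapply(seq_len(ncol(ranges)),
                                          function(j) ranges[, j])
  if (length(ranges) != 3) stop("three factor ranges required", call. = FALSE)
  for (r in ranges)
    if (r[1] > r[2]) stop("range lower bound exceeds upper bound", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  out <- vapply(ranges, function(r) runif(n, r[1], r[2]), numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, c("x1", "x2", "x3")))
  out
}

#' @rdname mc_sample_uniform
#' @export
default_mc_ranges <- function()
  list(x1 = c(0.05, 0.10), x2 = c(0.05, 0.10), x3 = c(0.05, 0.10))

#' Propagate sampled inoculum levels through a response model
#'
#' Evaluates the factorial model at each sampled triple. No residual noise
#' is added: the propagated spread reflects input uncertainty only.
#'
#' @param fit a `ferm_glm` (fitted or built with
#'   [factorial_coefficients()]).
#' @param samples matrix of inoculum triples, as from
#'   [mc_sample_uniform()].
#' @return Numeric vector of predictions, one per row of `samples`.
#' @export
mc_propagate <- function(fit, samples) {
  predict(fit, as.data.frame(samples))
}

#' Linear-interpolation percentile
#'
#' @param x numeric vector, non-empty.
#' @param q percentile in (0, 100); vectorised.
#' @return The empirical quantile(s) of `x` with linear interpolation
#'   between order statistics.
#' @examples
#' mc_percentile(1:5, 50)   # 3
#' @export
mc_percentile <- function(x, q) {
  if (!length(x)) stop("empty prediction vector", call. = FALSE)
  if (any(q <= 0 | q >= 100))
    stop("percentile must lie strictly between 0 and 100", call. = FALSE)
  quantile(x, probs = q / 100, type = 7, names = FALSE)
}

#' Per-factor sensitivity of propagated predictions
#'
#' Rank (Spearman) correlation between each sampled factor and the
#' predictions — the quantity displayed on a tornado chart — plus a
#' contribution-to-variation share: squared correlations normalised to sum
#' to 100% over the three factors.
#'
#' @param samples matrix of factor draws (columns `x1`, `x2`, `x3`).
#' @param predictions propagated model values, one per row.
#' @param method `"spearman"` (default, robust to the mild nonlinearity of
#'   interaction terms) or `"pearson"`.
#' @return A list with `correlation` and `contribution_pct`, both named by
#'   factor.
#' @export
mc_sensitivity <- function(samples, predictions,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (nrow(samples) < 3) stop("need at least 3 cases", call. = FALSE)
  if (sd(predictions) == 0)
    stop("undefined sensitivity: predictions have zero variance",
         call. = FALSE)
  r <- apply(samples, 2, function(col) {
    if (sd(col) == 0) 0 else cor(col, predictions, method = method)
  })
  r2 <- r^2
  contrib <- if (sum(r2) == 0) rep(NA_real_, length(r)) else 100 * r2 / sum(r2)
  list(correlation = r, contribution_pct = setNames(contrib, names(r)))
}

#' Monte Carlo uncertainty analysis of a factorial response model
#'
#' Samples inoculum triples uniformly, propagates them through the model,
#' and summarises the prediction distribution (percentiles) and per-factor
#' sensitivity (tornado correlations and contribution shares).
#'
#' @param fit a `ferm_glm`.
#' @param n number of simulated cases (1000 by convention).
#' @param ranges per-factor sampling ranges, see [mc_sample_uniform()].
#' @param seed integer seed for reproducibility.
#' @param probs percentiles of interest, in percent.
#' @param method correlation method for [mc_sensitivity()].
#' @return An object of class `ferm_mc`: `n_cases`, `seed`, `samples`,
#'   `predictions`, `percentiles` (named vector), `sensitivity`
#'   (correlations), `contribution_pct`.
#' @examples
#' m <- factorial_coefficients(c(`(Intercept)` = 3.44, x1 = 1.28,
#'                               x2 = 4.41, x3 = -2.73))
#' monte_carlo(m, n = 200, seed = 1)
#' @export
monte_carlo <- function(fit, n = 1000, ranges = default_mc_ranges(),
                        seed = NULL, probs = c(1, 5, 50, 95, 99),
                        method = "spearman") {
  samples <- mc_sample_uniform(n, ranges, seed = seed)
  pred <- mc_propagate(fit, samples)
  sens <- mc_sensitivity(samples, pred, method = method)
  structure(list(
    n_cases = n, seed = seed, samples = samples, predictions = pred,
    percentiles = setNames(mc_percentile(pred, probs),
                           paste0("p", probs)),
    sensitivity = sens$correlation,
    contribution_pct = sens$contribution_pct
  ), class = "ferm_mc")
}

#' @export
print.ferm_mc <- function(x, digits = 4, ...) {
  cat(sprintf("Monte Carlo propagation: %d cases%s\n", x$n_cases,
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  cat("Percentiles:\n"); print(round(x$percentiles, digits))
  cat("Factor correlation (tornado):\n"); print(round(x$sensitivity, digits))
  cat("Contribution to variation (%):\n")
  print(round(x$contribution_pct, 2))
  invisible(x)
}
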