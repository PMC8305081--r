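#' Design matrix for the factorial inoculum model
#'
#' Builds the regressor matrix of the identity-link response model
#' `Y = b0 + b1*x1 + b2*x2 + b3*x3 + b12*x1*x2 + b13*x1*x3 + b23*x2*x3`
#' (optionally plus the three-way product `x1*x2*x3`) in natural
#' (uncoded) inoculum concentration units. Natural units match the
#' published coefficient magnitudes: with levels of order 0.05-0.10%,
#' interaction coefficients land in the tens to thousands.
#'
#' @param levels matrix or data frame whose first three columns (or
#'   columns `x1`, `x2`, `x3`) give the inoculum levels.
#' @param three_way include the `x1:x2:x3` column.
#' @return Numeric matrix with columns `(Intercept)`, `x1`, `x2`, `x3`,
#'   `x1:x2`, `x1:x3`, `x2:x3` and optionally `x1:x2:x3`.
#' @examples
#' ferm_design_matrix(cbind(0.05, 0.05, 0.05))
#' @export
ferm_design_matrix <- function(levels, three_way = FALSE) {
  levels <- as.data.frame(levels)
  if (all(c("x1", "x2", "x3") %in% names(levels)))
    levels <- levels[c("x1", "x2", "x3")]
  if (ncol(levels) < 3) stop("three factor columns required", call. = FALSE)
  x1 <- levels[[1]]; x2 <- levels[[2]]; x3 <- levels[[3]]
  X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2, x3 = x3,
             `x1:x2` = x1 * x2, `x1:x3` = x1 * x3, `x2:x3` = x2 * x3)
  if (three_way) X <- cbind(X, `x1:x2:x3` = x1 * x2 * x3)
  X
}

#' Fit the factorial inoculum response model
#'
#' Ordinary least squares fit of the factorial model (see
#' [ferm_design_matrix()]) to the per-run response means of a
#' [ferm_design], with Gaussian identity-link inference: the dispersion
#' scale is `RSS / dof`, Wald 95% confidence intervals are
#' `estimate +/- z_{0.975} * SE`, and p-values are two-sided normal. The
#' default fit uses the cell means unweighted; non-intercept coefficients
#' are invariant to balanced replicate weighting.
#'
#' @param design a [ferm_design] (or data frame with `x1..x3` and
#'   `<response>_mean` columns).
#' @param response response name, e.g. `"tta_pct"`.
#' @param three_way include the three-way interaction (conventionally used
#'   for viscosity, where the joint culture effect is real).
#' @param weights optional per-run weights (e.g. replicate counts).
#' @return An object of class `ferm_glm` with a `coefficients` table
#'   (estimate, std_error, ci_lower, ci_upper, p_value per term), `scale`,
#'   `n_obs`, `dof_residual`, `three_way`, `fitted`, `residuals`;
#'   supports `coef()`, `predict()`, `confint()`, `summary()`, `print()`.
#' @examples
#' d <- ferm_fixture("starter_design")
#' fit <- fit_factorial(d, "tta_pct")
#' coef(fit)["x1:x2"]    # 32: the L. mesenteroides x P. pentosaceus synergy
#' @export
fit_factorial <- function(design, response, three_way = FALSE,
                          weights = NULL) {
  y <- design[[paste0(response, "_mean")]]
  if (is.null(y))
    stop(sprintf("response '%s' not present in design", response),
         call. = FALSE)
  X <- ferm_design_matrix(design, three_way = three_way)
  p <- ncol(X)
  if (nrow(X) < p)
    stop(sprintf("only %d distinct design points for %d model terms",
                 nrow(X), p), call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop(sprintf("rank-deficient design: collinear term(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, nrow(X)) else weights
  fit <- lm.wfit(X, y, w)
  est <- fit$coefficients
  res <- y - drop(X %*% est)
  dof <- nrow(X) - p
  rss <- sum(w * res^2)
  scale <- if (dof > 0) rss / dof else 0
  XtXinv <- chol2inv(chol(crossprod(X * sqrt(w))))
  se <- sqrt(pmax(diag(XtXinv) * scale, 0))
  z <- qnorm(0.975)
  zval <- ifelse(se > 0, est / se, ifelse(est == 0, 0, Inf * sign(est)))
  tab <- data.frame(
    term = colnames(X),
    estimate = unname(est),
    std_error = unname(se),
    ci_lower = unname(est - z * se),
    ci_upper = unname(est + z * se),
    p_value = unname(2 * pnorm(-abs(zval))),
    row.names = NULL
  )
  structure(list(coefficients = tab, scale = scale, n_obs = nrow(X),
                 dof_residual = dof, three_way = three_way,
                 response = response, fitted = drop(X %*% est),
                 residuals = res,
                 factor_names = attr(design, "factor_names") %||%
                   c("x1", "x2", "x3")),
            class = "ferm_glm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Factorial model object from known coefficients
#'
#' Wraps a published or otherwise externally supplied coefficient set as a
#' `ferm_glm` so it can be used with [predict.ferm_glm()] and
#' [monte_carlo()] without refitting. Standard errors, intervals and
#' p-values are absent.
#'
#' @param coefficients named numeric vector with names among
#'   `(Intercept)`, `x1`, `x2`, `x3`, `x1:x2`, `x1:x3`, `x2:x3`,
#'   `x1:x2:x3`; missing terms are taken as zero.
#' @param three_way whether the model carries the three-way product term.
#' @return A `ferm_glm` containing only estimates.
#' @examples
#' m <- factorial_coefficients(c(`(Intercept)` = 3.44, x1 = 1.28))
#' predict(m, data.frame(x1 = 0.075, x2 = 0.075, x3 = 0.075))
#' @export
factorial_coefficients <- function(coefficients, three_way = FALSE) {
  terms <- c("(Intercept)", "x1", "x2", "x3", "x1:x2", "x1:x3", "x2:x3",
             if (three_way) "x1:x2:x3")
  unknown <- setdiff(names(coefficients), terms)
  if (length(unknown))
    stop(sprintf("unknown term(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  est <- setNames(rep(0, length(terms)), terms)
  est[names(coefficients)] <- coefficients
  tab <- data.frame(term = terms, estimate = unname(est),
                    std_error = NA_real_, ci_lower = NA_real_,
                    ci_upper = NA_real_, p_value = NA_real_,
                    row.names = NULL)
  structure(list(coefficients = tab, scale = NA_real_, n_obs = NA_integer_,
                 dof_residual = NA_integer_, three_way = three_way,
                 response = NA_character_, fitted = NULL, residuals = NULL,
                 factor_names = c("x1", "x2", "x3")),
            class = "ferm_glm")
}

#' @export
coef.ferm_glm <- function(object, ...)
  setNames(object$coefficients$estimate, object$coefficients$term)

#' @export
confint.ferm_glm <- function(object, ...) {
  m <- as.matrix(object$coefficients[c("ci_lower", "ci_upper")])
  rownames(m) <- object$coefficients$term
  m
}

#' Predict from a factorial inoculum model
#'
#' @param object a `ferm_glm`.
#' @param newdata data frame (or matrix) with columns `x1`, `x2`, `x3`;
#'   defaults to the fitted design points.
#' @param ... unused.
#' @return Predicted response values.
#' @export
predict.ferm_glm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$fitted))
      stop("no fitted design points stored; supply newdata", call. = FALSE)
    return(object$fitted)
  }
  X <- ferm_design_matrix(newdata, three_way = object$three_way)
  drop(X %*% coef(object))
}

#' @export
print.ferm_glm <- function(x, digits = 4, ...) {
  cat(sprintf("Factorial inoculum response model%s%s\n",
              if (!is.na(x$response)) paste0(" for ", x$response) else "",
              if (x$three_way) " (with three-way term)" else ""))
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (!is.na(x$scale))
    cat(sprintf("(Scale) %.4g on %d residual dof\n", x$scale, x$dof_residual))
  invisible(x)
}

#' @export
summary.ferm_glm <- function(object, ...) object
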