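test_that("design matrix columns are the natural-unit regressors", {
  X <- ferm_design_matrix(cbind(0.05, 0.05, 0.05))
  expect_equal(unname(drop(X)),
               c(1, 0.05, 0.05, 0.05, 0.0025, 0.0025, 0.0025))
  Xc <- ferm_design_matrix(cbind(0.075, 0.075, 0.075), three_way = TRUE)
  expect_equal(unname(Xc[1, "x1:x2:x3"]), 0.075^3)
  expect_equal(unname(Xc[1, "x1:x2:x3"]), 4.21875e-4)
  d <- ferm_fixture("starter_design")
  X9 <- ferm_design_matrix(d)
  expect_equal(dim(X9), c(9, 7))
  expect_equal(qr(X9)$rank, 7)
})

test_that("factorial fit reproduces the published interaction coefficients", {
  d <- ferm_fixture("starter_design")
  # TTA: the x1:x2 synergy lands on 32 exactly from the 2-dp cell means
  tta <- fit_factorial(d, "tta_pct")
  expect_equal(unname(coef(tta)["x1:x2"]), 32, tolerance = 1e-8)
  # pH and viscosity interactions within 2% of the published values
  ph <- fit_factorial(d, "ph")
  expect_equal(unname(coef(ph)["x1:x2"]), -63.00, tolerance = 0.02)
  visc <- fit_factorial(d, "viscosity_mpas", three_way = TRUE)
  expect_equal(unname(coef(visc)["x1:x3"]), 4020.87, tolerance = 0.02)
  # Wald intervals bracket their estimates; dof accounting holds
  expect_true(all(tta$coefficients$ci_lower <= tta$coefficients$estimate))
  expect_true(all(tta$coefficients$estimate <= tta$coefficients$ci_upper))
  expect_equal(tta$dof_residual, 9 - 7)
  expect_gte(tta$scale, 0)
})

test_that("factorial fit matches a hand normal-equations oracle", {
  d <- ferm_fixture("starter_design")
  for (r in c("ph", "tta_pct", "viscosity_mpas")) {
    tw <- r == "viscosity_mpas"
    fit <- fit_factorial(d, r, three_way = tw)
    X <- ferm_design_matrix(d, three_way = tw)
    y <- d[[paste0(r, "_mean")]]
    beta <- solve(t(X) %*% X, t(X) %*% y)   # brute-force normal equations
    expect_equal(unname(coef(fit)), unname(drop(beta)), tolerance = 1e-8)
  }
})

test_that("noise-free synthetic responses invert exactly", {
  truth <- ferm_reference_glm()
  d <- synth_design(residual_sd = c(ph = 0, tta_pct = 0, viscosity_mpas = 0))
  for (r in names(truth)) {
    tw <- r == "viscosity_mpas"
    fit <- fit_factorial(d, r, three_way = tw)
    expect_equal(coef(fit), truth[[r]], tolerance = 1e-6)
    expect_equal(fit$scale, 0, tolerance = 1e-12)
    # prediction at a fitted design point equals the fitted value
    expect_equal(predict(fit, d), unname(predict(fit)), tolerance = 1e-9)
  }
})

test_that("centre points perturb only the intercept (orthogonality)", {
  corners <- default_design_points()[1:8, ]
  truth <- c(`(Intercept)` = 3.5, x1 = 1, x2 = -2, x3 = 0.5,
             `x1:x2` = -40, `x1:x3` = 25, `x2:x3` = -5)
  m <- factorial_coefficients(truth)
  mk <- function(pts, shift = 0) {
    df <- pts
    df$ph_mean <- predict(m, pts) + shift * (pts$x1 == 0.075)
    df$ph_sd <- 0.1; df$ph_n <- 3L
    ferm_design(df)
  }
  f8 <- fit_factorial(mk(corners), "ph")
  # add a centre observation displaced from the model surface
  with_centre <- rbind(corners, data.frame(x1 = 0.075, x2 = 0.075, x3 = 0.075))
  f9 <- fit_factorial(mk(with_centre, shift = 0.3), "ph")
  est8 <- coef(f8); est9 <- coef(f9)
  nonint <- setdiff(names(est8), "(Intercept)")
  expect_equal(est9[nonint], est8[nonint], tolerance = 1e-6)
  expect_false(isTRUE(all.equal(est9["(Intercept)"], est8["(Intercept)"],
                                tolerance = 1e-6)))
})

test_that("saturated corner model interpolates the corner means exactly", {
  d <- ferm_fixture("starter_design")
  corners <- d[d$x1 != 0.075, ]
  fit <- fit_factorial(corners, "viscosity_mpas", three_way = TRUE)
  expect_equal(unname(predict(fit)), corners$viscosity_mpas_mean,
               tolerance = 1e-9)
  expect_equal(fit$dof_residual, 0)
})

test_that("cell-mean fit equals balanced replicate-weighted fit", {
  d <- synth_design(seed = 11)
  for (r in c("ph", "viscosity_mpas")) {
    tw <- r == "viscosity_mpas"
    f1 <- fit_factorial(d, r, three_way = tw)
    f3 <- fit_factorial(d, r, three_way = tw,
                        weights = d[[paste0(r, "_n")]])
    expect_equal(coef(f1), coef(f3), tolerance = 1e-9)
  }
})

test_that("degenerate designs and responses are reported", {
  d <- ferm_fixture("starter_design")
  # constant response: zero non-intercept coefficients, zero scale
  dc <- as.data.frame(d)
  dc$flat_mean <- 4; dc$flat_sd <- 0; dc$flat_n <- 3L
  fit <- fit_factorial(ferm_design(dc), "flat")
  expect_equal(unname(coef(fit)[-1]), rep(0, 6), tolerance = 1e-9)
  expect_equal(fit$scale, 0, tolerance = 1e-12)
  # rank-deficient design (a factor held constant) names the terms
  bad <- as.data.frame(d); bad$x3 <- 0.05
  expect_error(fit_factorial(ferm_design(bad), "ph"), "collinear")
  expect_error(fit_factorial(d, "absent"), "not present")
  # three-way model on too few distinct points
  expect_error(fit_factorial(ferm_design(as.data.frame(d)[1:5, ]), "ph"),
               "design points")
})

test_that("published coefficient sets predict through the model surface", {
  m <- factorial_coefficients(ferm_reference_glm()$ph)
  centre <- predict(m, data.frame(x1 = 0.075, x2 = 0.075, x3 = 0.075))
  expect_equal(centre, 3.60, tolerance = 0.005)
  only_int <- factorial_coefficients(c(`(Intercept)` = 2))
  expect_equal(predict(only_int, data.frame(x1 = 1, x2 = 2, x3 = 3)), 2)
  expect_error(factorial_coefficients(c(bogus = 1)), "unknown term")
})
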