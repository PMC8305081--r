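test_that("eval_exponential follows its closed form", {
  # initial value a - b at t = 0
  expect_equal(eval_exponential(3.382, -3.188, 0.071, 0), 6.570)
  # asymptote as t grows
  expect_equal(eval_exponential(4, -2, 0.1, 1e6), 4)
  # b = 0 gives a constant curve
  expect_equal(eval_exponential(5, 0, 0.1, c(0, 7, 100)), rep(5, 3))
})

test_that("exponential fit reproduces the frozen reference on bundled pH/TTA", {
  ts <- ferm_fixture("slurry_timecourse")
  fit <- fit_exponential(ts$time_h, ts_means(ts, "ph"))
  expect_true(fit$converged)
  expect_equal(coef(fit), ref_ph_fit, tolerance = 1e-5)
  expect_equal(fit$r2, ref_ph_r2, tolerance = 1e-6)
  expect_length(residuals(fit), fit$n_points)
  # standard errors from the local linearisation match the nls oracle run
  expect_equal(unname(fit$se), c(0.2125990, 0.2032094, 0.0128709),
               tolerance = 1e-4)
  fit2 <- fit_exponential(ts$time_h, ts_means(ts, "tta_pct"))
  expect_equal(coef(fit2), ref_tta_fit, tolerance = 1e-5)
  expect_equal(fit2$r2, ref_tta_r2, tolerance = 1e-6)
})

test_that("exponential fit recovers noise-free truth exactly", {
  t <- seq(0, 36, 3)
  y <- eval_exponential(4, -2, 0.1, t)
  fit <- fit_exponential(t, y)
  expect_equal(coef(fit), c(a = 4, b = -2, c = 0.1), tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("exponential fit matches a dense grid-search oracle", {
  t <- c(0, 4, 8, 16, 24, 36)
  y <- eval_exponential(3.4, -3.2, 0.07, t) + c(0.05, -0.04, 0.02, -0.03, 0.01, 0)
  fit <- fit_exponential(t, y)
  rss_fit <- sum(residuals(fit)^2)
  grid <- expand.grid(a = seq(3.0, 3.8, 0.02), b = seq(-3.6, -2.8, 0.02),
                      c = seq(0.03, 0.12, 0.002))
  rss_grid <- min(vapply(seq_len(nrow(grid)), function(i)
    sum((y - eval_exponential(grid$a[i], grid$b[i], grid$c[i], t))^2),
    numeric(1)))
  expect_lte(rss_fit, rss_grid + 1e-8)
})

test_that("exponential fit rejects bad input and beats hand-supplied triples", {
  expect_error(fit_exponential(c(0, 3, 6), c(1, 2, 3)), "at least 4")
  expect_error(fit_exponential(c(0, 3, 3, 6), c(1, 2, 3, 4)),
               "strictly increasing")
  ts <- ferm_fixture("slurry_timecourse")
  y <- ts_means(ts, "ph")
  fit <- fit_exponential(ts$time_h, y)
  for (triple in list(c(3.38, -3.19, 0.071), c(3.4, -3.0, 0.08),
                      c(3.0, -3.5, 0.05))) {
    hand <- eval_exponential(triple[1], triple[2], triple[3], ts$time_h)
    expect_gte(fit$r2, r_squared(y, hand))
  }
})

test_that("converged exponential predictions are monotone and bounded", {
  ts <- ferm_fixture("slurry_timecourse")
  for (v in c("ph", "tta_pct")) {
    fit <- fit_exponential(ts$time_h, ts_means(ts, v))
    p <- coef(fit)
    expect_gt(p["c"], 0)
    grid <- predict(fit, seq(0, 60, 0.5))
    expect_true(all(diff(grid) < 0) || all(diff(grid) > 0))
    lo <- min(p["a"], p["a"] - p["b"]); hi <- max(p["a"], p["a"] - p["b"])
    expect_true(all(grid >= lo - 1e-9 & grid <= hi + 1e-9))
  }
})

test_that("fits on cell means equal fits on balanced replicate-expanded data", {
  t <- seq(0, 36, 3)
  y <- eval_exponential(3.4, -3.2, 0.07, t) + sin(t) * 0.03
  ex <- expand_replicates(t, y, n = 3)
  # balanced expansion has tied times; fit the expanded data by weighting
  f_means <- fit_exponential(t, y)
  f_wt <- fit_exponential(t, y, weights = rep(3, length(t)))
  expect_equal(coef(f_means), coef(f_wt), tolerance = 1e-7)
  # quadratic: expanded OLS equals weighted OLS on means equals plain means
  q_means <- fit_quadratic(t, y)
  q_exp <- fit_quadratic(ex$t, ex$y)
  expect_equal(coef(q_means), coef(q_exp), tolerance = 1e-9)
})

test_that("quadratic fit reproduces the bundled glucose kinetics", {
  ts <- ferm_fixture("slurry_timecourse")
  y <- ts_means(ts, "glucose_pct")
  fit <- fit_quadratic(ts$time_h, y)
  expect_equal(fit$r2, ref_glu_r2, tolerance = 1e-6)
  expect_equal(unname(coef(fit)),
               c(0.595824176, 0.103621379, -0.001817627), tolerance = 1e-6)
  # the refit cannot be beaten by the printed rounded coefficients
  printed <- 0.584 + 0.107 * ts$time_h - 0.002 * ts$time_h^2
  expect_gte(fit$r2, r_squared(y, printed))
})

test_that("quadratic fit handles exact and degenerate cases", {
  # collinear points: c2 = 0 exactly, r2 = 1
  fit <- fit_quadratic(c(0, 1, 2, 3), c(1, 3, 5, 7))
  expect_equal(unname(coef(fit)["c2"]), 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_error(fit_quadratic(c(2, 2, 2), c(1, 2, 3)), "singular")
  expect_error(fit_quadratic(c(0, 1), c(1, 2)), "at least 3")
})

test_that("r_squared implements 1 - RSS/CSS", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  o <- c(2, 4, 9, 1)
  expect_equal(r_squared(o, rep(mean(o), 4)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_lt(r_squared(c(1, 2, 3), c(3, 2, 1)), 0)   # worse than the mean
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(r_squared(1:3, 1:4), "length")
})

test_that("titration conversion follows the lactic acid formula", {
  expect_equal(tta_percent(0), 0)
  expect_equal(tta_percent(1.33, 0.1, 10), 1.33 * 0.1 * 90.08 / 10000 * 100)
  expect_equal(tta_percent(1.33, 0.1, 10), 0.1198, tolerance = 1e-3)
  # doubling the sample volume halves the result
  expect_equal(tta_percent(2, 0.1, 20), tta_percent(2, 0.1, 10) / 2)
  expect_error(tta_percent(1, 0.1, 0), "positive")
  expect_error(tta_percent(-1), "non-negative")
})

test_that("plateau detection finds the stabilisation time", {
  ts <- ferm_fixture("slurry_timecourse")
  # earliest time from which all consecutive Welch comparisons fail at 0.05;
  # frozen from the hand-computed Welch p ladder on the bundled pH summary,
  # consistent with no significant change from 18 h onward
  expect_equal(plateau_time(ts, "ph", alpha = 0.05), 12)
  expect_gte(plateau_time(ts, "ph", alpha = 0.10), 12)
  # constant series stabilises immediately
  const <- ferm_timeseries(data.frame(time_h = c(0, 3, 6),
                                      ph_mean = c(4, 4, 4),
                                      ph_sd = c(0.1, 0.1, 0.1), ph_n = 3))
  expect_equal(plateau_time(const, "ph"), 0)
  # large steps with tiny SDs never plateau
  steep <- ferm_timeseries(data.frame(time_h = c(0, 3, 6, 9),
                                      ph_mean = c(7, 6, 5, 4),
                                      ph_sd = rep(0.001, 4), ph_n = 3))
  expect_equal(plateau_time(steep, "ph"), 9)
  # missing sd -> insufficient replication
  nas <- ferm_timeseries(data.frame(time_h = c(0, 3), ph_mean = c(4, 4),
                                    ph_sd = c(0.1, NA), ph_n = 3))
  expect_error(plateau_time(nas, "ph"), "insufficient replication")
})
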