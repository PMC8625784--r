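table1_points <- data.frame(S = c(1288, 934, 763, 525, 348),
                            Q = c(2.0, 1.0, 0.5, 0.25, 0.125))

test_that("exact quadratic-through-origin data are recovered to 1e-9 relative", {
  a <- 2e-6; b <- 3e-4
  S <- c(200, 500, 900, 1300)
  pts <- data.frame(S = S, Q = a * S^2 + b * S)
  for (w in c("none", "inverse_Q", "inverse_Q2")) {
    fit <- fit_calibration(pts, weighting = w)
    expect_equal(fit$a, a, tolerance = 1e-9)
    expect_equal(fit$b, b, tolerance = 1e-9)
    expect_equal(fit$relative_deviation_pct, 0, tolerance = 1e-7)
  }
})

test_that("serial-dilution calibration points give finite origin-anchored fits", {
  for (w in c("none", "inverse_Q", "inverse_Q2")) {
    fit <- fit_calibration(table1_points, weighting = w)
    expect_true(is.finite(fit$a) && is.finite(fit$b))
    expect_identical(predict_content(fit, 0), 0)
  }
})

test_that("the solver agrees with an independent normal-equations oracle to 1e-8", {
  datasets <- list(
    table1_points,
    data.frame(S = c(120, 340, 780, 1500, 2600),
               Q = c(0.11, 0.4, 1.1, 2.9, 6.4)))
  for (pts in datasets) {
    for (w in c("none", "inverse_Q", "inverse_Q2")) {
      wts <- switch(w, none = rep(1, nrow(pts)),
                    inverse_Q = 1 / pts$Q, inverse_Q2 = 1 / pts$Q^2)
      oracle <- calib_normal_equations(pts$S, pts$Q, wts)
      fit <- fit_calibration(pts, weighting = w)
      expect_equal(fit$a, unname(oracle["a"]), tolerance = 1e-8)
      expect_equal(fit$b, unname(oracle["b"]), tolerance = 1e-8)
    }
  }
})

test_that("rescaling areas rescales unweighted coefficients as a/c^2, b/c", {
  pts <- table1_points
  fit1 <- fit_calibration(pts, weighting = "none")
  c_ <- 7.3
  pts2 <- data.frame(S = c_ * pts$S, Q = pts$Q)
  fit2 <- fit_calibration(pts2, weighting = "none")
  expect_equal(fit2$a, fit1$a / c_^2, tolerance = 1e-10)
  expect_equal(fit2$b, fit1$b / c_, tolerance = 1e-10)
})

test_that("degenerate calibration inputs are refused", {
  expect_error(fit_calibration(data.frame(S = c(1, 2), Q = c(1, 2))),
               "at least 3")
  expect_error(fit_calibration(data.frame(S = c(5, 5, 5), Q = c(1, 2, 3))),
               "at least 3|distinct")
  expect_error(fit_calibration(data.frame(S = 1:4, Q = c(-1, 1, 2, 3))),
               "Q > 0")
})

test_that("the reported calibration equation reproduces its worked example", {
  model <- calibration_model(a = 0.1e-5, b = 2.6e-4)
  q <- predict_content(model, 1288)
  expect_equal(signif(q, 2), 2.0)
  # strictly increasing for positive coefficients
  s <- seq(0, 3000, by = 10)
  expect_true(all(diff(predict_content(model, s)) > 0))
  expect_error(predict_content(model, -5), "non-negative")
})

test_that("calibration inversion is the algebraic inverse", {
  model <- calibration_model(a = 0.1e-5, b = 2.6e-4)
  expect_identical(invert_calibration(model, 0), 0)
  for (S in c(10, 1e3, 1e5))
    expect_equal(invert_calibration(model, predict_content(model, S)), S,
                 tolerance = 1e-9)
  lin <- calibration_model(a = 0, b = 2.6e-4)
  expect_equal(invert_calibration(lin, 0.26), 1000)
  expect_error(invert_calibration(calibration_model(0, 0), 1), "not both")
})

test_that("relative deviation is zero iff the points lie on the curve", {
  a <- 1.5e-6; b <- 2e-4
  S <- c(300, 700, 1100, 1600)
  exact <- data.frame(S = S, Q = a * S^2 + b * S)
  expect_equal(fit_calibration(exact)$relative_deviation_pct, 0,
               tolerance = 1e-7)
  off <- exact; off$Q[2] <- off$Q[2] * 1.2
  expect_gt(fit_calibration(off)$relative_deviation_pct, 0.5)
  expect_gt(fit_calibration(off, deviation = "max")$relative_deviation_pct,
            fit_calibration(off)$relative_deviation_pct)
})

test_that("anchors on an exact log-linear law are reproduced by both ladder modes", {
  mws <- c(116, 85, 66.2, 45, 35, 25, 18.4)
  slope <- -1.2; intercept <- 2.3
  rf <- (intercept - log10(mws)) / (-slope)  # invert log10(mw) = i + s*rf
  front <- 400L
  apex <- rf * front
  lad_ll <- fit_ladder(apex, mws, front, mode = "loglinear")
  expect_equal(lad_ll$slope, slope, tolerance = 1e-9)
  expect_equal(lad_ll$intercept, intercept, tolerance = 1e-9)
  expect_equal(as.numeric(estimate_mw(lad_ll, apex, front)), mws,
               tolerance = 1e-9)
  lad_pw <- fit_ladder(apex, mws, front, mode = "piecewise")
  expect_equal(as.numeric(estimate_mw(lad_pw, apex, front)), mws,
               tolerance = 1e-12)
})

test_that("piecewise queries between anchors return the geometric mean at midpoint", {
  apex <- c(100, 200)
  mws <- c(90, 30)
  lad <- fit_ladder(apex, mws, 400, mode = "piecewise")
  expect_equal(as.numeric(estimate_mw(lad, 150, 400)), sqrt(90 * 30),
               tolerance = 1e-12)
})

test_that("removing an interior anchor only changes piecewise estimates between its neighbours", {
  mws <- c(116, 85, 66.2, 45, 35, 25, 18.4, 14.4)
  apex <- seq(50, 360, length.out = 8)
  front <- 400L
  full <- fit_ladder(apex, mws, front, mode = "piecewise")
  drop <- fit_ladder(apex[-4], mws[-4], front, mode = "piecewise")
  grid <- seq(51, 359, by = 2)
  mw_full <- as.numeric(estimate_mw(full, grid, front))
  mw_drop <- as.numeric(estimate_mw(drop, grid, front))
  inside <- grid > apex[3] & grid < apex[5]
  expect_equal(mw_full[!inside], mw_drop[!inside], tolerance = 1e-12)
  expect_gt(max(abs(mw_full[inside] - mw_drop[inside])), 0)
})

test_that("estimate_mw is strictly decreasing in rf over the anchor range (property)", {
  mws <- c(116, 85, 66.2, 45, 35, 25, 18.4, 14.4)
  apex <- c(48, 94, 132, 189, 227, 277, 323, 359)
  front <- 400L
  grid <- seq(48, 359, by = 1)
  for (mode in c("piecewise", "loglinear")) {
    lad <- fit_ladder(apex, mws, front, mode = mode)
    est <- as.numeric(estimate_mw(lad, grid, front))
    expect_true(all(diff(est) < 0))
  }
})

test_that("ladder inputs are validated", {
  expect_error(fit_ladder(c(50, 100), c(30, 80), 400),
               "decreasing")
  expect_error(fit_ladder(c(50, 100), c(80, 30), 90), "front_row")
  expect_error(fit_ladder(c(50, 100, 150), c(80, 30), 400), "equal counts")
  lad <- fit_ladder(c(50, 100), c(80, 30), 400)
  expect_error(estimate_mw(lad, 450, 400), "front_row")
  expect_error(predict(lad, 1.5), "rf")
})

test_that("extrapolation beyond the anchor range is flagged", {
  lad <- fit_ladder(c(100, 200, 300), c(100, 50, 20), 400)
  mw <- estimate_mw(lad, c(50, 150, 350), 400)
  expect_equal(attr(mw, "extrapolated"), c(TRUE, FALSE, TRUE))
})

test_that("degradation degree obeys its boundary cases and worked arithmetic", {
  expect_equal(degradation_degree(500, 500)$alpha_pct, 0)
  expect_equal(degradation_degree(500, 0)$alpha_pct, 100)
  expect_equal(degradation_degree(1288, 103.04)$alpha_pct, 92.0)
  expect_error(degradation_degree(0, 1), "positive")
  expect_error(degradation_degree(-2, 1), "positive")
  expect_warning(degradation_degree(100, 120), "gain")
})

test_that("degradation degree is unit-free and antitone in St (property)", {
  set.seed(7)
  for (i in 1:25) {
    S0 <- runif(1, 10, 1e4)
    St <- runif(2, 0, S0)
    St <- sort(St)
    a_lo <- degradation_degree(S0, St[2])$alpha_pct
    a_hi <- degradation_degree(S0, St[1])$alpha_pct
    expect_gte(a_hi, a_lo)
    c_ <- runif(1, 0.01, 100)
    expect_equal(degradation_degree(c_ * S0, c_ * St[1])$alpha_pct, a_hi,
                 tolerance = 1e-12)
  }
})
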