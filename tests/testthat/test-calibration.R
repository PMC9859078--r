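test_that("noiseless quartic data are recovered to numerical precision", {
  b <- ref_coefs("allele")
  x <- seq(1.5, 4, length.out = 25)
  fit <- vp_calibrate(data.frame(x = x, y = poly_eval(b, x)),
                      parameter_type = "allele")
  expect_equal(unname(coef(fit)), b, tolerance = 1e-8)
  expect_lt(fit$residual_sd, 1e-10)
})

test_that("OLS agrees with the brute-force normal-equations oracle", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(9:50, 1)
    x <- runif(n, 1, 4.5)
    y <- rnorm(n, sin(x), 0.3)
    fit <- vp_calibrate(data.frame(x = x, y = y), parameter_type = "allele")
    expect_equal(unname(coef(fit)), ne_poly_fit(x, y, 4), tolerance = 1e-8)
    # residuals sum to zero and are orthogonal to every design column
    r <- residuals(fit)
    X <- outer(x, 0:4, `^`)
    expect_lt(max(abs(t(X) %*% r)) / n, 1e-6)
  }
})

test_that("constant response degenerates gracefully", {
  x <- seq(1, 4, length.out = 10)
  w <- capture_warnings(
    fit <- vp_calibrate(data.frame(x = x, y = rep(2.5, 10)),
                        parameter_type = "allele"))
  expect_match(w, "zero total variance", all = FALSE)
  expect_equal(unname(coef(fit)), c(2.5, 0, 0, 0, 0), tolerance = 1e-8)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 0)
})

test_that("rank-deficient or undersized designs are rejected", {
  expect_error(
    vp_calibrate(data.frame(x = rep(1:4, 5), y = rnorm(20)),
                 parameter_type = "allele"),
    "distinct x")
  expect_error(
    vp_calibrate(data.frame(x = 1:6, y = rnorm(6)),
                 parameter_type = "allele"),
    "at least")
})

test_that("prediction matches direct evaluation of reference coefficients", {
  ref <- reference_calibration()
  expect_equal(predict(ref$allele, 0, warn_extrapolation = FALSE), 5.5312)
  expect_equal(predict(ref$allele, 3, warn_extrapolation = FALSE), 0.5593,
               tolerance = 1e-10)
  expect_equal(predict(ref$reverse_stutter, 0, warn_extrapolation = FALSE),
               -13.404)
  expect_equal(predict(ref$forward_stutter, 0, warn_extrapolation = FALSE),
               -0.1678)
  # upper band adds exactly the offset
  expect_equal(predict(ref$allele, 3, what = "upper",
                       warn_extrapolation = FALSE),
               0.5593 + 0.2156, tolerance = 1e-10)
  expect_warning(predict(ref$allele, 5), "extrapolation")
})

test_that("empirical band offset is z times the residual SD", {
  for (case in list(c(sd = 0.2156 / 2.326, off = 0.2156),
                    c(sd = 0.2755 / 2.326, off = 0.2755),
                    c(sd = 0.1779 / 2.326, off = 0.1779))) {
    m <- reference_calibration()$allele
    m$residual_sd <- case[["sd"]]
    band <- empirical_band(m, z = 2.326)
    expect_equal(band$offset, case[["off"]], tolerance = 1e-4)
  }
  m <- reference_calibration()$allele
  m$residual_sd <- 0
  expect_equal(predict_upper(empirical_band(m), 2.5,
                             warn_extrapolation = FALSE),
               predict(m, 2.5, warn_extrapolation = FALSE))
  expect_error(empirical_band(m, z = -1), "z must")
})

test_that("Jarque-Bera matches hand-computed moments", {
  jb <- jarque_bera(c(-1, 0, 1))  # S = 0, K = 1.5, n = 3
  expect_equal(jb$statistic, 0.28125, tolerance = 1e-12)
  # symmetric sample constructed to have kurtosis exactly 3:
  # c(-a,-1,-1,-1,1,1,1,a) with a^4 - 18 a^2 - 15 = 0
  a <- sqrt((18 + sqrt(18^2 + 4 * 15)) / 2)
  jb0 <- jarque_bera(c(-a, -1, -1, -1, 1, 1, 1, a))
  expect_equal(jb0$statistic, 0, tolerance = 1e-12)
  expect_equal(jb0$p_value, 1)
  expect_error(jarque_bera(rep(2, 10)), "zero variance")
  expect_error(jarque_bera(c(1, 2)), "at least 3")
})

test_that("Jarque-Bera holds its nominal size on normal samples", {
  set.seed(41)
  pvals <- replicate(200, jarque_bera(rnorm(1e4))$p_value)
  expect_gte(mean(pvals > 0.01), 0.99)
})

test_that("R^2 never decreases from degree 3 to degree 4", {
  set.seed(51)
  for (i in 1:10) {
    x <- runif(40, 1, 4)
    y <- rnorm(40, 0.3 * x^2 - x, 0.4)
    f3 <- vp_calibrate(data.frame(x = x, y = y), "allele", degree = 3)
    f4 <- vp_calibrate(data.frame(x = x, y = y), "allele", degree = 4)
    expect_gte(f4$r_squared + 1e-12, f3$r_squared)
  }
})

test_that("simulated calibration data recover truth", {
  set.seed(61)
  b <- ref_coefs("allele")
  x <- runif(500, 1.5, 4.2)
  y <- poly_eval(b, x) + rnorm(500, 0, 0.0927)
  fit <- vp_calibrate(data.frame(x = x, y = y), "allele")
  expect_equal(fit$residual_sd, 0.0927, tolerance = 0.1)
  # fitted trend close to truth across the range
  xs <- seq(1.6, 4.1, length.out = 50)
  expect_lt(max(abs(predict(fit, xs, warn_extrapolation = FALSE) -
                      poly_eval(b, xs))), 0.05)
})

test_that("calibration artifacts round-trip through JSON", {
  rec <- generate_records(300, seed = 5)
  cal <- vp_calibrate_all(rec)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  for (pt in vp_parameter_types()) {
    expect_equal(unname(back[[pt]]$coefficients),
                 unname(cal[[pt]]$coefficients))
    expect_equal(back[[pt]]$residual_sd, cal[[pt]]$residual_sd)
    expect_equal(back[[pt]]$offset, cal[[pt]]$offset)
    expect_equal(back[[pt]]$x_range, cal[[pt]]$x_range)
    # restored calibrations predict identically
    xs <- seq(1.6, 4, length.out = 11)
    expect_equal(predict(back[[pt]], xs, warn_extrapolation = FALSE),
                 predict(cal[[pt]], xs, warn_extrapolation = FALSE))
  }
})

test_that("calibration summary exposes OLS inference", {
  rec <- generate_records(400, seed = 8)
  fit <- vp_calibrate(rec, "allele")
  expect_equal(fit$n, 400)
  expect_true(fit$r_squared > 0 && fit$r_squared < 1)
  expect_lt(fit$f_pvalue, 0.01)
  expect_equal(dim(fit$coef_ci99), c(5, 2))
  expect_true(all(fit$coef_ci99[, 1] < coef(fit) &
                    coef(fit) < fit$coef_ci99[, 2]))
  expect_output(print(summary(fit)), "Jarque-Bera")
})
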