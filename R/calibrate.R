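# Calibration of the empirical working range: ordinary least squares
# polynomial regression of log10(variance parameter) on log10(Tc), with
# residual diagnostics and a one-sided upper band at mean + z * residual SD.

#' Calibrate the empirical working range for one variance parameter
#'
#' Fits a polynomial regression (degree 4 by default) of
#' y = log10(variance parameter) on x = log10(Tc) by unweighted ordinary
#' least squares, pooling all replicate interpretations as independent
#' points. The fitted trend plus `z` residual standard deviations forms the
#' empirical upper working limit; with the default z = 2.326 that is a
#' one-sided 99th-percentile band under normal residuals.
#'
#' Degree 4 is the default because variance-versus-template trends are
#' distinctly nonlinear across the usual Tc range; the degree is exposed to
#' permit model exploration. The residual SD uses the unbiased
#' n - (degree + 1) denominator.
#'
#' @param points Either a data frame with numeric columns `x` and `y` (as
#'   returned by [to_log_points()]) or a `vp_records` data frame (then
#'   `parameter_type` selects the variance column and x, y are computed).
#' @param parameter_type One of [vp_parameter_types()]; required when
#'   `points` is a `vp_records` object, otherwise taken from the points if
#'   present.
#' @param degree Polynomial degree; default 4.
#' @param z Multiplier on the residual SD for the upper band. Fixed at
#'   2.326 by default (the conventional rounded one-sided 99% normal
#'   multiplier) rather than `qnorm(0.99)` so band arithmetic reproduces
#'   published working-range offsets exactly; configurable.
#'
#' @return An object of class `vp_calibration` with components
#'   `coefficients` (named `b0`..`b<degree>`, `b<degree>` the highest-order
#'   term), `residual_sd`, `offset` (= z * residual_sd), `n`, `r_squared`,
#'   `f_statistic`, `f_pvalue`, `coef_table`, `coef_ci99`, `jb_statistic`,
#'   `jb_pvalue`, `x_range` and the data and residuals.
#' @seealso [predict.vp_calibration()], [empirical_band()], [jarque_bera()],
#'   [reference_calibration()]
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(60, 1.5, 4.2)
#' y <- 0.5 - 0.1 * x + 0.02 * x^2 + rnorm(60, 0, 0.1)
#' fit <- vp_calibrate(data.frame(x = x, y = y), parameter_type = "allele")
#' coef(fit)
#' predict(fit, c(2, 3), what = "upper")
vp_calibrate <- function(points, parameter_type = NULL, degree = 4,
                         z = 2.326) {
  if (inherits(points, "vp_records")) {
    if (is.null(parameter_type)) {
      stop("parameter_type is required when calibrating from records")
    }
    points <- to_log_points(points, parameter_type)
  }
  if (is.null(parameter_type)) {
    parameter_type <- if (!is.null(points$parameter_type)) {
      unique(as.character(points$parameter_type))[1]
    } else "allele"
  }
  parameter_type <- match.arg(parameter_type, vp_parameter_types())
  stopifnot(is.numeric(points$x), is.numeric(points$y))
  x <- as.numeric(points$x)
  y <- as.numeric(points$y)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite")
  }
  degree <- as.integer(degree)
  if (degree < 1) stop("degree must be >= 1")
  n <- length(x)
  p <- degree + 1L
  if (n < p + 2L) {
    stop("need at least ", p + 2L, " points for a degree-", degree,
         " calibration (>= 2 residual df)")
  }
  if (length(unique(x)) < p) {
    stop("need at least ", p, " distinct x values for a degree-", degree,
         " fit; got ", length(unique(x)))
  }
  if (!is.finite(z) || z <= 0) stop("z must be > 0")

  X <- stats::poly(x, degree, raw = TRUE)
  cond <- kappa(cbind(1, X), exact = FALSE)
  if (cond > 1e12) {
    warning("polynomial design is severely ill-conditioned (kappa ~ ",
            format(cond, digits = 3), "); coefficients may be unstable")
  }
  fit <- stats::lm(y ~ X)
  beta <- unname(stats::coef(fit))
  names(beta) <- paste0("b", 0:degree)
  res <- unname(stats::residuals(fit))
  sm <- summary(fit)
  residual_sd <- sqrt(sum(res^2) / (n - p))

  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12 * max(1, mean(y)^2) * n) {
    warning("response has (near) zero total variance; r_squared set to 0")
    r_squared <- 0
    f_statistic <- NA_real_
    f_pvalue <- NA_real_
  } else {
    r_squared <- sm$r.squared
    f_statistic <- unname(sm$fstatistic[1])
    f_pvalue <- stats::pf(sm$fstatistic[1], sm$fstatistic[2],
                          sm$fstatistic[3], lower.tail = FALSE)
  }

  ct <- sm$coefficients
  rownames(ct) <- names(beta)[seq_len(nrow(ct))]
  ci <- stats::confint(fit, level = 0.99)
  rownames(ci) <- rownames(ct)

  jb <- tryCatch(jarque_bera(res),
                 error = function(e) list(statistic = NA_real_,
                                          p_value = NA_real_))

  structure(list(
    parameter_type = parameter_type,
    degree = degree,
    coefficients = beta,
    residual_sd = residual_sd,
    z = z,
    offset = z * residual_sd,
    n = n,
    r_squared = r_squared,
    f_statistic = f_statistic,
    f_pvalue = unname(f_pvalue),
    coef_table = ct,
    coef_ci99 = ci,
    jb_statistic = jb$statistic,
    jb_pvalue = jb$p_value,
    x_range = range(x),
    x = x, y = y,
    fitted = unname(stats::fitted(fit)),
    residuals = res,
    source = "fitted"
  ), class = "vp_calibration")
}

#' Calibrate all three variance parameters at once
#'
#' @param records A `vp_records` data frame; only rows with
#'   `dataset == "unchallenged"` are used unless `use_all = TRUE` (working
#'   ranges are defined from unchallenged interpretations).
#' @param use_all Use every record regardless of dataset label.
#' @inheritParams vp_calibrate
#' @return A named list of three `vp_calibration` objects, class
#'   `vp_calibration_set`.
#' @export
vp_calibrate_all <- function(records, degree = 4, z = 2.326,
                             use_all = FALSE) {
  validate_vp_records(records)
  if (!use_all) {
    records <- records[records$dataset == "unchallenged", , drop = FALSE]
    if (nrow(records) == 0) stop("no unchallenged records to calibrate from")
  }
  out <- lapply(vp_parameter_types(), function(pt) {
    vp_calibrate(records, parameter_type = pt, degree = degree, z = z)
  })
  names(out) <- vp_parameter_types()
  class(out) <- "vp_calibration_set"
  out
}

# Horner evaluation of b0 + b1 x + ... + bk x^k
horner <- function(coefficients, x) {
  acc <- rep(0, length(x))
  for (b in rev(coefficients)) acc <- acc * x + b
  acc
}

#' Predict the calibrated trend or its upper band
#'
#' Evaluates the fitted polynomial (Horner scheme) at new log10(Tc) values.
#' `what = "upper"` adds the one-sided band offset `z * residual_sd`.
#' Values outside the calibration `x_range` trigger an extrapolation
#' warning (not an error: casework Tc can exceed the calibrated range).
#'
#' @param object A `vp_calibration`.
#' @param x Numeric vector of log10(Tc) values.
#' @param what `"mean"` for the regression line, `"upper"` for the band.
#' @param warn_extrapolation Emit a warning for x outside `x_range`.
#' @param ... Unused.
#' @return Numeric vector of predicted log10(variance parameter).
#' @export
predict.vp_calibration <- function(object, x, what = c("mean", "upper"),
                                   warn_extrapolation = TRUE, ...) {
  what <- match.arg(what)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("x must be finite")
  if (warn_extrapolation &&
      any(x < object$x_range[1] | x > object$x_range[2])) {
    warning("predicting outside the calibration range [",
            format(object$x_range[1], digits = 4), ", ",
            format(object$x_range[2], digits = 4), "] (extrapolation)")
  }
  out <- horner(object$coefficients, x)
  if (what == "upper") out <- out + object$offset
  out
}

#' One-sided empirical band of a calibration
#'
#' Packages a calibration with its band multiplier; the band offset is
#' exactly `z * residual_sd` in log10 units.
#'
#' @param model A `vp_calibration`.
#' @param z Positive band multiplier; default 2.326.
#' @return An object of class `empirical_band` with fields `model`, `z`,
#'   `offset`.
#' @export
empirical_band <- function(model, z = 2.326) {
  stopifnot(inherits(model, "vp_calibration"))
  if (!is.finite(z) || z <= 0) stop("z must be > 0")
  structure(list(model = model, z = z, offset = z * model$residual_sd),
            class = "empirical_band")
}

#' @rdname empirical_band
#' @param band An `empirical_band` (or a `vp_calibration`, using its own z).
#' @param x log10(Tc) values.
#' @param ... Passed to [predict.vp_calibration()].
#' @export
predict_upper <- function(band, x, ...) {
  if (inherits(band, "vp_calibration")) band <- empirical_band(band, band$z)
  stopifnot(inherits(band, "empirical_band"))
  predict(band$model, x, what = "mean", ...) + band$offset
}

#' Jarque-Bera test for normality
#'
#' The classic moment-estimator form: JB = (n/6) (S^2 + (K - 3)^2 / 4)
#' with sample skewness S and kurtosis K computed from central moments
#' (biased, 1/n denominators), referred to an asymptotic chi-square
#' distribution with 2 df. Small-sample Monte-Carlo p-values are not
#' implemented; at calibration sample sizes the asymptotic reference is
#' standard practice.
#'
#' @param residuals Numeric vector, length >= 3, nonzero variance.
#' @return List with `statistic` and `p_value`.
#' @export
#' @examples
#' jarque_bera(rnorm(200))
jarque_bera <- function(residuals) {
  r <- as.numeric(residuals)
  n <- length(r)
  if (n < 3) stop("need at least 3 residuals")
  if (any(!is.finite(r))) stop("residuals must be finite")
  m <- mean(r)
  m2 <- mean((r - m)^2)
  if (m2 <= 0) stop("residuals have zero variance")
  s <- mean((r - m)^3) / m2^1.5
  k <- mean((r - m)^4) / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb,
       p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Reference calibration from published working-range coefficients
#'
#' Ships the degree-4 coefficients and band offsets of a completed
#' GlobalFiler / STRmix v2.8 validation as a ready-made calibration set, so
#' flagging can be exercised without refitting. Residual SDs are recovered
#' from the published band offsets as offset / 2.326. Inference fields that
#' require the raw calibration data (R^2, F, t, CIs, Jarque-Bera) are `NA`.
#'
#' @param x_range Assumed calibration range of log10(Tc); default
#'   `c(1.5, 4.2)`, spanning the template levels of the source validation.
#' @return A `vp_calibration_set` of three reference `vp_calibration`
#'   objects.
#' @export
reference_calibration <- function(x_range = c(1.5, 4.2)) {
  z <- 2.326
  spec <- list(
    allele = list(
      coefficients = c(b0 = 5.5312, b1 = -8.2618, b2 = 4.8535,
                       b3 = -1.2206, b4 = 0.1122),
      offset = 0.2156),
    reverse_stutter = list(
      coefficients = c(b0 = -13.404, b1 = 23.456, b2 = -13.619,
                       b3 = 3.3258, b4 = -0.2892),
      offset = 0.2755),
    forward_stutter = list(
      coefficients = c(b0 = -0.1678, b1 = 1.7016, b2 = -1.0891,
                       b3 = 0.313, b4 = -0.0348),
      offset = 0.1779)
  )
  out <- lapply(names(spec), function(pt) {
    s <- spec[[pt]]
    structure(list(
      parameter_type = pt,
      degree = 4L,
      coefficients = s$coefficients,
      residual_sd = s$offset / z,
      z = z,
      offset = s$offset,
      n = NA_integer_,
      r_squared = NA_real_,
      f_statistic = NA_real_,
      f_pvalue = NA_real_,
      coef_table = NULL,
      coef_ci99 = NULL,
      jb_statistic = NA_real_,
      jb_pvalue = NA_real_,
      x_range = as.numeric(x_range),
      x = numeric(0), y = numeric(0),
      fitted = numeric(0), residuals = numeric(0),
      source = "reference"
    ), class = "vp_calibration")
  })
  names(out) <- names(spec)
  class(out) <- "vp_calibration_set"
  out
}

#' @export
coef.vp_calibration <- function(object, ...) object$coefficients

#' @export
residuals.vp_calibration <- function(object, ...) object$residuals

#' @export
fitted.vp_calibration <- function(object, ...) object$fitted

#' @export
print.vp_calibration <- function(x, ...) {
  cat(sprintf("Variance-parameter calibration (%s), degree %d [%s]\n",
              x$parameter_type, x$degree, x$source))
  cat("  coefficients (b0 = intercept):\n")
  print(signif(x$coefficients, 6))
  cat(sprintf("  residual SD = %.4f; upper band = trend + %.3f * SD = +%.4f\n",
              x$residual_sd, x$z, x$offset))
  cat(sprintf("  calibration range: log10(Tc) in [%.3g, %.3g]\n",
              x$x_range[1], x$x_range[2]))
  invisible(x)
}

#' @export
summary.vp_calibration <- function(object, ...) {
  structure(object, class = c("summary.vp_calibration", "vp_calibration"))
}

#' @export
print.summary.vp_calibration <- function(x, ...) {
  print.vp_calibration(x)
  if (!is.na(x$r_squared)) {
    cat(sprintf("  n = %d, R^2 = %.4f, F p-value = %.3g\n",
                x$n, x$r_squared, x$f_pvalue))
  }
  if (!is.null(x$coef_table)) {
    cat("  coefficient inference (99% CIs):\n")
    tab <- cbind(x$coef_table[, c("Estimate", "Std. Error", "Pr(>|t|)")],
                 x$coef_ci99)
    print(signif(tab, 4))
  }
  if (!is.na(x$jb_pvalue)) {
    cat(sprintf("  Jarque-Bera residual normality: JB = %.4f, p = %.4f\n",
                x$jb_statistic, x$jb_pvalue))
  }
  invisible(x)
}

#' @export
print.vp_calibration_set <- function(x, ...) {
  for (m in x) print(m)
  invisible(x)
}

#' Plot a calibration with its benchmark lines
#'
#' Scatter of the calibration points with the fitted trend (solid red), the
#' empirical upper band (dashed red) and, when priors are supplied, the
#' prior gamma mode (solid black) and upper quantile (dashed black) lines.
#'
#' @param x A `vp_calibration`.
#' @param prior Optional `gamma_prior` or `prior_benchmarks` for the same
#'   parameter type.
#' @param points Optional data frame with `x`, `y` to overlay instead of
#'   the calibration data (e.g. a challenged dataset against unchallenged
#'   bands).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vp_calibration <- function(x, prior = NULL, points = NULL, ...) {
  model <- x
  if (is.null(points)) {
    points <- data.frame(x = model$x, y = model$y)
  }
  xs <- seq(model$x_range[1], model$x_range[2], length.out = 200)
  mean_line <- predict(model, xs, warn_extrapolation = FALSE)
  upper_line <- mean_line + model$offset
  ylim <- range(c(points$y, mean_line, upper_line), finite = TRUE)
  if (inherits(prior, "gamma_prior")) prior <- prior_bands(prior)
  if (!is.null(prior)) {
    ylim <- range(c(ylim, prior$log10_mode, prior$log10_q_upper),
                  na.rm = TRUE)
  }
  graphics::plot(points$x, points$y,
                 xlab = expression(log[10](Tc)),
                 ylab = expression(log[10]("variance parameter")),
                 main = model$parameter_type, pch = 16,
                 col = grDevices::adjustcolor("grey30", 0.5),
                 ylim = ylim, ...)
  graphics::lines(xs, mean_line, col = "red", lwd = 2)
  graphics::lines(xs, upper_line, col = "red", lwd = 2, lty = 2)
  if (!is.null(prior)) {
    if (!is.na(prior$log10_mode)) {
      graphics::abline(h = prior$log10_mode, col = "black", lwd = 2)
    }
    graphics::abline(h = prior$log10_q_upper, col = "black", lwd = 2,
                     lty = 2)
  }
  invisible(model)
}

#' Serialize / restore a calibration set
#'
#' Writes the fields needed for flagging (coefficients, residual SD, z,
#' x_range, degree) to human-readable JSON so flagging can run without
#' refitting; data and inference fields are not serialized. Reading back
#' yields reference-style calibrations.
#'
#' @param calibrations A `vp_calibration_set` (or single `vp_calibration`).
#' @param path JSON file path.
#' @return `read_calibration` returns a `vp_calibration_set`.
#' @export
write_calibration <- function(calibrations, path) {
  if (inherits(calibrations, "vp_calibration")) {
    calibrations <- structure(stats::setNames(list(calibrations),
                                              calibrations$parameter_type),
                              class = "vp_calibration_set")
  }
  payload <- lapply(calibrations, function(m) {
    list(parameter_type = m$parameter_type, degree = m$degree,
         coefficients = as.list(m$coefficients),
         residual_sd = m$residual_sd, z = m$z, x_range = m$x_range)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(payload, function(m) {
    cf <- unlist(m$coefficients)
    structure(list(
      parameter_type = m$parameter_type,
      degree = as.integer(m$degree),
      coefficients = cf,
      residual_sd = m$residual_sd,
      z = m$z,
      offset = m$z * m$residual_sd,
      n = NA_integer_, r_squared = NA_real_,
      f_statistic = NA_real_, f_pvalue = NA_real_,
      coef_table = NULL, coef_ci99 = NULL,
      jb_statistic = NA_real_, jb_pvalue = NA_real_,
      x_range = as.numeric(m$x_range),
      x = numeric(0), y = numeric(0),
      fitted = numeric(0), residuals = numeric(0),
      source = "restored"
    ), class = "vp_calibration")
  })
  names(out) <- vapply(out, `[[`, character(1), "parameter_type")
  class(out) <- "vp_calibration_set"
  out
}
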