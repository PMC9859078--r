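# Prior gamma benchmarks: the constant (Tc-independent) reference lines
# derived from the prior gamma distribution of each variance parameter.

#' Prior gamma distribution of a variance parameter
#'
#' During validation, probabilistic-genotyping software builds a gamma prior
#' for each variance parameter from a training set of single-source
#' profiles; its mode and upper quantiles serve as constant benchmarks for
#' the per-interpretation averages.
#'
#' IMPORTANT: `beta` is the SCALE parameter, not the rate. Gamma
#' parameterizations are a classic trap; the scale convention here is the
#' one under which mode = (alpha - 1) * beta, which is how the shipped
#' reference priors reproduce their documented modes.
#'
#' @param parameter_type One of [vp_parameter_types()].
#' @param alpha Shape parameter, > 0 (unitless).
#' @param beta Scale parameter, > 0 (units of the variance parameter).
#' @return An object of class `gamma_prior`.
#' @export
#' @examples
#' gamma_prior("allele", alpha = 3.891, beta = 1.131)
gamma_prior <- function(parameter_type, alpha, beta) {
  parameter_type <- match.arg(parameter_type, vp_parameter_types())
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  if (!is.finite(beta) || beta <= 0) stop("beta must be > 0")
  structure(list(parameter_type = parameter_type, alpha = alpha, beta = beta),
            class = "gamma_prior")
}

#' Reference prior gamma parameters
#'
#' The (shape, scale) pairs shipped as the default benchmarks for the three
#' variance parameters, as printed on v2.8-era interpretation reports from
#' the calibrating laboratory's validation. Override with priors from your
#' own validation when available.
#'
#' @return Named list of three `gamma_prior` objects.
#' @export
default_priors <- function() {
  list(
    allele = gamma_prior("allele", alpha = 3.891, beta = 1.131),
    reverse_stutter = gamma_prior("reverse_stutter", alpha = 1.557,
                                  beta = 6.436),
    forward_stutter = gamma_prior("forward_stutter", alpha = 1.526,
                                  beta = 4.552)
  )
}

#' Mode of a gamma prior
#'
#' Under the scale parameterization the mode is `(alpha - 1) * beta` for
#' `alpha > 1` and 0 otherwise (density peaks at the origin).
#'
#' @param prior A `gamma_prior`.
#' @return Nonnegative numeric mode.
#' @export
gamma_mode <- function(prior) {
  stopifnot(inherits(prior, "gamma_prior"))
  if (prior$alpha > 1) (prior$alpha - 1) * prior$beta else 0
}

#' Quantile of a gamma prior
#'
#' @param prior A `gamma_prior`.
#' @param p Probability in (0, 1); defaults to 0.99, the conventional upper
#'   benchmark, but the choice is not fundamental.
#' @return The value q with `P(X <= q) = p` under
#'   `Gamma(shape = alpha, scale = beta)`.
#' @export
gamma_quantile <- function(prior, p = 0.99) {
  stopifnot(inherits(prior, "gamma_prior"))
  if (any(!is.finite(p) | p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  stats::qgamma(p, shape = prior$alpha, scale = prior$beta)
}

#' Constant benchmark lines from a gamma prior
#'
#' Computes the prior's mode and upper quantile together with their log10
#' values, the horizontal benchmark lines drawn on log10(variance) versus
#' log10(Tc) plots. When the mode is 0 (shape <= 1) the mode line is
#' undefined in log space and mode-based flagging is disabled with a
#' warning.
#'
#' @param prior A `gamma_prior`.
#' @param p Upper quantile probability (default 0.99).
#' @return An object of class `prior_benchmarks` with fields
#'   `parameter_type`, `mode`, `q_upper`, `p`, `log10_mode` (possibly `NA`)
#'   and `log10_q_upper`.
#' @export
#' @examples
#' prior_bands(gamma_prior("allele", 3.891, 1.131))
prior_bands <- function(prior, p = 0.99) {
  mode <- gamma_mode(prior)
  q <- gamma_quantile(prior, p)
  if (mode == 0) {
    warning("prior mode is 0 (shape <= 1): mode benchmark disabled for ",
            prior$parameter_type)
    log10_mode <- NA_real_
  } else {
    log10_mode <- log10(mode)
  }
  structure(list(parameter_type = prior$parameter_type, mode = mode,
                 q_upper = q, p = p, log10_mode = log10_mode,
                 log10_q_upper = log10(q)),
            class = "prior_benchmarks")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf("Gamma prior (%s): shape = %.4g, scale = %.4g\n",
              x$parameter_type, x$alpha, x$beta))
  cat(sprintf("  mode = %.4g, 99th percentile = %.4g\n",
              gamma_mode(x), gamma_quantile(x, 0.99)))
  invisible(x)
}

#' @export
print.prior_benchmarks <- function(x, ...) {
  cat(sprintf("Prior benchmarks (%s): mode = %.4g, %g%% quantile = %.4g\n",
              x$parameter_type, x$mode, 100 * x$p, x$q_upper))
  invisible(x)
}
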