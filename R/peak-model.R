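# Lognormal peak-height variance model: the log10 ratio of observed to
# modeled peak height is normal with mean 0 and variance equal to the
# variance parameter divided by the relevant peak height, so spread grows
# with the variance parameter and shrinks with peak height.

#' Simulate peak observations under the lognormal variance model
#'
#' Draws log10(observed / expected) independently from
#' N(0, variance_param / relevant_height) for each supplied relevant
#' height. The relevant height equals the expected height for alleles (and
#' for stutters modeled on expected stutter height); for -1 stutter modeled
#' on the parent allele it is the parent's observed height. The simulator
#' treats it as a given positive value either way.
#'
#' @param variance_param Positive variance parameter (unitless; RFU-scaled
#'   by the division).
#' @param relevant_heights Vector of positive peak heights in RFU.
#' @param expected_heights Expected peak heights in RFU; defaults to
#'   `relevant_heights`.
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame with columns `expected_height`, `observed_height`,
#'   `relevant_height` and `log10_ratio`.
#' @export
#' @examples
#' pk <- simulate_peaks(3.27, rep(1000, 5), seed = 1)
#' sd(pk$log10_ratio)  # about sqrt(3.27 / 1000)
simulate_peaks <- function(variance_param, relevant_heights,
                           expected_heights = relevant_heights,
                           seed = NULL) {
  if (!is.finite(variance_param) || variance_param <= 0) {
    stop("variance_param must be > 0")
  }
  relevant_heights <- as.numeric(relevant_heights)
  expected_heights <- as.numeric(expected_heights)
  if (length(relevant_heights) == 0 ||
      any(!is.finite(relevant_heights) | relevant_heights <= 0)) {
    stop("relevant_heights must be positive")
  }
  if (length(expected_heights) != length(relevant_heights) ||
      any(!is.finite(expected_heights) | expected_heights <= 0)) {
    stop("expected_heights must be positive and match relevant_heights")
  }
  if (!is.null(seed)) set.seed(seed)
  sdlog <- sqrt(variance_param / relevant_heights)
  ratio <- stats::rnorm(length(relevant_heights), mean = 0, sd = sdlog)
  data.frame(
    expected_height = expected_heights,
    observed_height = expected_heights * 10^ratio,
    relevant_height = relevant_heights,
    log10_ratio = ratio
  )
}

#' Estimate a variance parameter from peak observations
#'
#' Maximum-likelihood inversion of the lognormal model: with each
#' log10 ratio ~ N(0, c2 / h), the MLE is the mean of
#' h_i * log10(observed_i / expected_i)^2. (The MCMC machinery that samples
#' this quantity in the genotyping software is out of scope; this is the
#' closed-form estimator for known peak pairs.)
#'
#' @param observations Data frame with columns `observed_height`,
#'   `expected_height` and `relevant_height` (as from [simulate_peaks()]).
#' @return Nonnegative variance parameter estimate.
#' @export
estimate_variance_param <- function(observations) {
  req <- c("observed_height", "expected_height", "relevant_height")
  stopifnot(is.data.frame(observations), all(req %in% names(observations)))
  if (nrow(observations) < 2) stop("need at least 2 observations")
  h <- observations$relevant_height
  obs <- observations$observed_height
  exp_ <- observations$expected_height
  if (any(!is.finite(h) | h <= 0) || any(!is.finite(obs) | obs <= 0) ||
      any(!is.finite(exp_) | exp_ <= 0)) {
    stop("heights must be positive and finite")
  }
  mean(h * log10(obs / exp_)^2)
}

#' Convert between Tc and log10(Tc); expected stutter heights
#'
#' Small conveniences for reasoning about detection-threshold effects:
#' `tc_from_log10` inverts the plotting transform, and
#' `expected_stutter_heights` gives the stutter peak heights implied by a
#' parent template and a range of stutter ratios (stutter peaks near or
#' below the analytical threshold are where stutter variance trends change
#' regime).
#'
#' @param x log10(Tc) value(s).
#' @return `tc_from_log10`: Tc in RFU.
#' @export
#' @examples
#' tc_from_log10(2.79)                     # ~617 RFU
#' expected_stutter_heights(617, c(0.05, 0.1))  # ~31-62 RFU
tc_from_log10 <- function(x) 10^as.numeric(x)

#' @rdname tc_from_log10
#' @param tc Template (RFU) of the parent contributor.
#' @param ratios Stutter ratio(s), e.g. 0.05-0.1 for -1 repeat stutter.
#' @export
expected_stutter_heights <- function(tc, ratios) {
  tc <- as.numeric(tc)
  ratios <- as.numeric(ratios)
  if (any(!is.finite(tc) | tc <= 0)) stop("tc must be positive")
  if (any(!is.finite(ratios) | ratios <= 0)) stop("ratios must be positive")
  outer_vals <- outer(tc, ratios)
  if (length(tc) == 1) drop(outer_vals) else outer_vals
}
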