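# Synthetic interpretation-record generator. Emulates the statistical
# structure the working-range analysis assumes: a quartic mean trend in
# log-log space, homoscedastic normal residuals in log10 units, and
# challenge-specific additive shifts. It works at the diagnostic-summary
# level (no electropherograms, alleles or mixture ratios are simulated).

#' Default challenge shifts for the generator
#'
#' Per-dataset additive offsets (log10 units) applied to each variance
#' parameter's trend, encoding the characteristic directions of the
#' challenge conditions: inhibition elevates reverse stutter most (stutter
#' dropout must be modeled across the profile) while leaving allele
#' variance largely unchanged; NOC underestimation and cell-line mixtures
#' elevate allele variance most; degradation moderately elevates allele and
#' reverse stutter; signal saturation elevates all three, reverse stutter
#' the most. Magnitudes are set by one-sided normal tail arithmetic so the
#' nominal generator reproduces the direction and rough ordering of
#' published exceedance rates — exact percentages depend on the real data
#' and are deliberately not a generator target.
#'
#' @return Named list (dataset label -> named numeric of offsets per
#'   parameter type).
#' @export
default_challenge_shifts <- function() {
  shift <- function(a, r, f) {
    c(allele = a, reverse_stutter = r, forward_stutter = f)
  }
  list(
    unchallenged = shift(0, 0, 0),
    inhibited    = shift(0.05, 0.30, 0.10),
    noc_under    = shift(0.16, 0.06, 0.04),
    degraded     = shift(0.14, 0.19, 0.09),
    saturated    = shift(0.19, 0.38, 0.22),
    cell_line    = shift(0.14, 0.03, 0.00),
    other        = shift(0, 0, 0)
  )
}

#' Specification for the synthetic record generator
#'
#' @param n_records Number of records to generate.
#' @param dataset Dataset label for every generated record; see
#'   [vp_dataset_labels()].
#' @param trends Named list (per parameter type) of
#'   `list(coefficients, residual_sd)` giving the mean polynomial in
#'   log-log space and the residual SD in log10 units. Defaults to the
#'   shipped [reference_calibration()] trends and SDs.
#' @param tc_log10_range Bounds for log10(Tc), drawn uniformly (log-uniform
#'   Tc gives even coverage of the regression domain). Default
#'   `c(1.5, 4.2)`.
#' @param challenge_shifts Per-dataset offsets; default
#'   [default_challenge_shifts()].
#' @param noc_range Candidate true contributor numbers; default `1:4`.
#' @param seed Optional integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_records, dataset = "unchallenged",
                           trends = NULL,
                           tc_log10_range = c(1.5, 4.2),
                           challenge_shifts = default_challenge_shifts(),
                           noc_range = 1:4, seed = NULL) {
  dataset <- match.arg(dataset, vp_dataset_labels())
  n_records <- as.integer(n_records)
  if (n_records < 1) stop("n_records must be >= 1")
  if (is.null(trends)) {
    ref <- reference_calibration()
    trends <- lapply(ref, function(m) {
      list(coefficients = m$coefficients, residual_sd = m$residual_sd)
    })
  }
  missing <- setdiff(vp_parameter_types(), names(trends))
  if (length(missing) > 0) {
    stop("trends missing parameter type(s): ", paste(missing, collapse = ", "))
  }
  for (pt in vp_parameter_types()) {
    t <- trends[[pt]]
    if (!is.numeric(t$coefficients) || length(t$coefficients) < 1) {
      stop("invalid trend coefficients for ", pt)
    }
    if (!is.finite(t$residual_sd) || t$residual_sd < 0) {
      stop("residual_sd must be >= 0 for ", pt)
    }
  }
  tc_log10_range <- as.numeric(tc_log10_range)
  if (length(tc_log10_range) != 2 || diff(tc_log10_range) <= 0) {
    stop("tc_log10_range must be ordered bounds")
  }
  sh <- challenge_shifts[[dataset]]
  if (is.null(sh) || !all(vp_parameter_types() %in% names(sh)) ||
      any(!is.finite(sh))) {
    stop("challenge_shifts must supply finite offsets for '", dataset, "'")
  }
  if (dataset == "noc_under" && max(noc_range) < 2) {
    stop("noc_under generation needs contributor numbers >= 2")
  }
  structure(list(n_records = n_records, dataset = dataset, trends = trends,
                 tc_log10_range = tc_log10_range,
                 challenge_shifts = challenge_shifts,
                 noc_range = as.integer(noc_range), seed = seed),
            class = "generator_spec")
}

#' Generate synthetic interpretation records
#'
#' Per record: log10(Tc) is drawn uniformly within the spec bounds; for
#' each parameter type, log10(variance) = trend(log10 Tc) + challenge
#' shift + N(0, residual_sd^2), independently across the three parameters
#' (no cross-correlation is modeled — a documented simplification).
#' Contributor templates are filled with Tc as the maximum plus smaller
#' dummy contributors consistent with the assumed contributor number.
#' Deterministic under a fixed seed.
#'
#' @param spec A `generator_spec`, or the number of records (then the
#'   remaining arguments are passed to [generator_spec()]).
#' @param ... Passed to [generator_spec()] when `spec` is a count.
#' @return A `vp_records` data frame.
#' @export
#' @examples
#' rec <- generate_records(50, dataset = "inhibited", seed = 7)
#' table(rec$dataset)
generate_records <- function(spec, ...) {
  if (!inherits(spec, "generator_spec")) {
    spec <- generator_spec(spec, ...)
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_records
  x <- stats::runif(n, spec$tc_log10_range[1], spec$tc_log10_range[2])
  tc <- 10^x
  shifts <- spec$challenge_shifts[[spec$dataset]]
  vars <- lapply(vp_parameter_types(), function(pt) {
    tr <- spec$trends[[pt]]
    y <- horner(tr$coefficients, x) + shifts[[pt]] +
      stats::rnorm(n, 0, tr$residual_sd)
    10^y
  })
  names(vars) <- vp_parameter_types()

  noc_true <- sample(spec$noc_range, n, replace = TRUE)
  if (spec$dataset == "noc_under") {
    noc_true <- pmax(noc_true, 2L)
    noc_assumed <- noc_true - 1L
  } else {
    noc_assumed <- noc_true
  }
  templates <- lapply(seq_len(n), function(i) {
    k <- noc_assumed[i]
    if (k == 1) return(tc[i])
    # minor contributors at 5-80% of Tc, decreasing
    c(tc[i], sort(tc[i] * stats::runif(k - 1, 0.05, 0.8), decreasing = TRUE))
  })

  vp_records(
    sample_id = sprintf("%s_%05d", spec$dataset, seq_len(n)),
    dataset = spec$dataset,
    noc_true = noc_true,
    noc_assumed = noc_assumed,
    contributor_templates = templates,
    allele_var = vars$allele,
    rev_stutter_var = vars$reverse_stutter,
    fwd_stutter_var = vars$forward_stutter
  )
}

#' Generate a multi-dataset study
#'
#' Convenience wrapper producing one combined `vp_records` data frame with
#' the given number of records per dataset label.
#'
#' @param n_per_dataset Named integer vector (dataset label -> count).
#' @param seed Integer seed (each dataset gets a distinct derived seed).
#' @param ... Passed to [generator_spec()].
#' @return A `vp_records` data frame.
#' @export
generate_study <- function(n_per_dataset, seed = NULL, ...) {
  stopifnot(length(n_per_dataset) > 0, !is.null(names(n_per_dataset)))
  parts <- lapply(seq_along(n_per_dataset), function(i) {
    ds_seed <- if (is.null(seed)) NULL else (seed + i - 1L) %% .Machine$integer.max
    generate_records(generator_spec(n_per_dataset[[i]],
                                    dataset = names(n_per_dataset)[i],
                                    seed = ds_seed, ...))
  })
  out <- do.call(rbind, parts)
  class(out) <- c("vp_records", "data.frame")
  rownames(out) <- NULL
  out
}

#' Simulate new responses from a fitted calibration
#'
#' Parametric resampling: draws log10(variance) values from the fitted
#' trend plus normal residual noise at the supplied (or original) design
#' points. Useful for bootstrap checks of the band construction.
#'
#' @param object A `vp_calibration`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param x Design points (log10 Tc); defaults to the calibration data.
#' @param ... Unused.
#' @return Data frame with one column per simulation.
#' @export
simulate.vp_calibration <- function(object, nsim = 1, seed = NULL,
                                    x = object$x, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (length(x) == 0) stop("no design points available; supply x")
  mu <- predict(object, x, warn_extrapolation = FALSE)
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(x), 0,
                                                         object$residual_sd)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
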