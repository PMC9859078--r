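# Advisory flagging of interpretations against four benchmark lines:
# the calibrated regression, the empirical upper band, the prior gamma
# mode and the prior gamma upper quantile. Flags prompt closer scrutiny;
# they are never hard stop points and no record is rejected.

#' Flag interpretation records against benchmark lines
#'
#' For each record and each variance parameter, compares
#' y = log10(variance parameter) at x = log10(Tc) against four lines:
#' the calibrated regression trend, the empirical upper band
#' (trend + z * residual SD), and the constant log10 prior-gamma mode and
#' upper-quantile lines. "Exceeds" means strictly greater (ties do not
#' flag: conservative, since a value exactly on a line carries no evidence
#' of elevation). The empirical lines depend on Tc, so the same variance
#' value can flag at one template level and not at another.
#'
#' Records with Tc outside the calibration range are still classified but
#' marked `extrapolated`.
#'
#' @param records A `vp_records` data frame.
#' @param calibrations A `vp_calibration_set` (or named list of
#'   `vp_calibration`) covering all three parameter types.
#' @param priors Named list of `gamma_prior` or `prior_benchmarks` objects
#'   per parameter type; default [default_priors()].
#' @param p Upper quantile probability for the prior benchmark (default
#'   0.99), used when `priors` are `gamma_prior` objects.
#'
#' @return A data frame of class `vp_flags`, one row per record x
#'   parameter type, with columns `sample_id`, `dataset`,
#'   `parameter_type`, `x`, `y`, `exceeds_regression`,
#'   `exceeds_empirical_99`, `exceeds_prior_mode`, `exceeds_prior_99`,
#'   `extrapolated`. When a prior mode is 0 its mode column is `NA`
#'   (benchmark disabled).
#' @export
#' @examples
#' cal <- reference_calibration()
#' rec <- vp_records("case1", "other", 2, 2, list(c(6882, 700)),
#'                   allele_var = 2.9, rev_stutter_var = 7.5,
#'                   fwd_stutter_var = 5.1)
#' flag_records(rec, cal)
flag_records <- function(records, calibrations, priors = default_priors(),
                         p = 0.99) {
  validate_vp_records(records)
  types <- vp_parameter_types()
  missing_cal <- setdiff(types, names(calibrations))
  if (length(missing_cal) > 0) {
    stop("missing calibration for parameter type(s): ",
         paste(missing_cal, collapse = ", "))
  }
  missing_pri <- setdiff(types, names(priors))
  if (length(missing_pri) > 0) {
    stop("missing prior for parameter type(s): ",
         paste(missing_pri, collapse = ", "))
  }
  benches <- lapply(types, function(pt) {
    pr <- priors[[pt]]
    if (inherits(pr, "gamma_prior")) pr <- prior_bands(pr, p)
    if (!inherits(pr, "prior_benchmarks")) {
      stop("priors[['", pt, "']] must be a gamma_prior or prior_benchmarks")
    }
    pr
  })
  names(benches) <- types

  x <- log10(tc_of(records))
  out <- lapply(types, function(pt) {
    model <- calibrations[[pt]]
    stopifnot(inherits(model, "vp_calibration"))
    y <- log10(records[[vp_var_column(pt)]])
    trend <- predict(model, x, warn_extrapolation = FALSE)
    upper <- trend + model$offset
    bench <- benches[[pt]]
    data.frame(
      sample_id = records$sample_id,
      dataset = records$dataset,
      parameter_type = pt,
      x = x, y = y,
      exceeds_regression = y > trend,
      exceeds_empirical_99 = y > upper,
      exceeds_prior_mode = if (is.na(bench$log10_mode)) NA else
        y > bench$log10_mode,
      exceeds_prior_99 = y > bench$log10_q_upper,
      extrapolated = x < model$x_range[1] | x > model$x_range[2],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("vp_flags", "data.frame")
  n_extra <- sum(out$extrapolated) / length(types)
  if (n_extra > 0) {
    message(n_extra, " record(s) have Tc outside the calibration range ",
            "(flagged as extrapolated)")
  }
  out
}

#' Summarize exceedance percentages per dataset
#'
#' Tabulates, for every dataset label x parameter type x benchmark, the
#' percentage of interpretations whose variance parameter exceeds the
#' benchmark line, with the underlying counts. A dataset that tracks the
#' calibration conditions is expected to put about half its points above
#' the trend lines (regression, prior mode) and only a small percentage
#' above the upper lines.
#'
#' @param flags A `vp_flags` data frame from [flag_records()].
#' @return A data frame of class `vp_exceedance` with columns
#'   `parameter_type`, `benchmark` (one of `regression`, `empirical_99`,
#'   `prior_mode`, `prior_99`), one percentage column per dataset present
#'   (2-decimal rounding applied by the print method, not the values) and
#'   an `n_<dataset>` count column per dataset.
#' @export
summarize_exceedance <- function(flags) {
  stopifnot(is.data.frame(flags), nrow(flags) > 0)
  benchmarks <- c(regression = "exceeds_regression",
                  empirical_99 = "exceeds_empirical_99",
                  prior_mode = "exceeds_prior_mode",
                  prior_99 = "exceeds_prior_99")
  datasets <- intersect(vp_dataset_labels(), unique(flags$dataset))
  types <- intersect(vp_parameter_types(), unique(flags$parameter_type))
  rows <- expand.grid(benchmark = names(benchmarks),
                      parameter_type = types,
                      stringsAsFactors = FALSE)[, 2:1]
  out <- rows
  for (ds in datasets) {
    pct <- numeric(nrow(rows))
    nn <- integer(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      sub <- flags[flags$dataset == ds &
                     flags$parameter_type == rows$parameter_type[i],
                   benchmarks[[rows$benchmark[i]]]]
      sub <- sub[!is.na(sub)]
      nn[i] <- length(sub)
      pct[i] <- if (length(sub) > 0) 100 * mean(sub) else NA_real_
    }
    out[[ds]] <- pct
    out[[paste0("n_", ds)]] <- nn
  }
  class(out) <- c("vp_exceedance", "data.frame")
  out
}

#' @export
print.vp_exceedance <- function(x, digits = 2, ...) {
  cat("Percentage of variance parameter values exceeding benchmark lines\n")
  show <- as.data.frame(x)
  pct_cols <- setdiff(names(show),
                      c("parameter_type", "benchmark",
                        grep("^n_", names(show), value = TRUE)))
  for (col in pct_cols) {
    show[[col]] <- sprintf(paste0("%.", digits, "f%%"), show[[col]])
  }
  print(show[, c("parameter_type", "benchmark", pct_cols)],
        row.names = FALSE)
  invisible(x)
}

#' @export
print.vp_flags <- function(x, ...) {
  cat("Benchmark flags:", nrow(x), "rows (",
      length(unique(x$sample_id)), "records x",
      length(unique(x$parameter_type)), "parameter types )\n")
  flagged <- x$exceeds_empirical_99
  cat(sprintf("  above empirical upper band: %d (%.2f%%)\n",
              sum(flagged), 100 * mean(flagged)))
  if (any(x$extrapolated)) {
    cat("  extrapolated (Tc outside calibration range):",
        sum(x$extrapolated), "rows\n")
  }
  invisible(x)
}
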