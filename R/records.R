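# Interpretation records: the per-run diagnostics exported from a
# probabilistic-genotyping interpretation report (one row per replicate
# interpretation).

#' Recognized variance parameter types
#'
#' The three universal variance parameters reported per interpretation:
#' allele, reverse (-1 repeat) stutter and forward (+1 repeat) stutter.
#'
#' @return Character vector of the three parameter type labels.
#' @export
vp_parameter_types <- function() {
  c("allele", "reverse_stutter", "forward_stutter")
}

#' Recognized dataset / challenge labels
#'
#' @return Character vector of dataset labels. `"unchallenged"` is the
#'   calibration set; the others are challenge conditions.
#' @export
vp_dataset_labels <- function() {
  c("unchallenged", "inhibited", "noc_under", "degraded", "saturated",
    "cell_line", "other")
}

# column holding each parameter type's variance
vp_var_column <- function(parameter_type) {
  parameter_type <- match.arg(parameter_type, vp_parameter_types())
  switch(parameter_type,
    allele = "allele_var",
    reverse_stutter = "rev_stutter_var",
    forward_stutter = "fwd_stutter_var")
}

#' Construct a set of interpretation records
#'
#' Builds a validated `vp_records` data frame, one row per replicate
#' interpretation. Replicate interpretations of the same amplification are
#' separate rows; all downstream analyses pool them as independent points.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param dataset Dataset labels; see [vp_dataset_labels()].
#' @param noc_true True number of contributors (positive integers).
#' @param noc_assumed Number of contributors assumed at interpretation.
#'   Must equal `noc_true` except for `"noc_under"` records, where it must
#'   be strictly smaller.
#' @param contributor_templates List of numeric vectors: the per-contributor
#'   template amounts in RFU from the interpretation report. Tc is derived
#'   from these (never stored) as the maximum.
#' @param allele_var,rev_stutter_var,fwd_stutter_var Positive average
#'   variance parameters for the interpretation.
#'
#' @return A data frame of class `vp_records`.
#' @export
#' @examples
#' vp_records("s1", "unchallenged", 2, 2, list(c(1500, 300)),
#'            allele_var = 3.1, rev_stutter_var = 6.2, fwd_stutter_var = 4.9)
vp_records <- function(sample_id, dataset, noc_true, noc_assumed,
                       contributor_templates, allele_var, rev_stutter_var,
                       fwd_stutter_var) {
  if (!is.list(contributor_templates)) {
    contributor_templates <- list(contributor_templates)
  }
  df <- data.frame(
    sample_id = as.character(sample_id),
    dataset = as.character(dataset),
    noc_true = as.integer(noc_true),
    noc_assumed = as.integer(noc_assumed),
    allele_var = as.numeric(allele_var),
    rev_stutter_var = as.numeric(rev_stutter_var),
    fwd_stutter_var = as.numeric(fwd_stutter_var),
    stringsAsFactors = FALSE
  )
  df$contributor_templates <- lapply(contributor_templates, as.numeric)
  class(df) <- c("vp_records", "data.frame")
  validate_vp_records(df)
  df
}

#' Validate interpretation records
#'
#' Checks every row against the record invariants: positive variances,
#' non-empty positive template lists, recognized dataset labels, and the
#' contributor-number consistency rule (`noc_assumed < noc_true` only for
#' `"noc_under"` rows). Errors name the offending row(s).
#'
#' @param records A `vp_records` data frame.
#' @return `records`, invisibly, if valid.
#' @export
validate_vp_records <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("sample_id", "dataset", "noc_true", "noc_assumed",
                "contributor_templates", "allele_var", "rev_stutter_var",
                "fwd_stutter_var")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  bad_row <- function(cond, msg) {
    idx <- which(cond)
    if (length(idx) > 0) {
      stop(msg, " in row(s): ", paste(utils::head(idx, 10L), collapse = ", "),
           call. = FALSE)
    }
  }
  bad_row(!records$dataset %in% vp_dataset_labels(),
          "unrecognized dataset label")
  for (col in c("allele_var", "rev_stutter_var", "fwd_stutter_var")) {
    v <- records[[col]]
    bad_row(!is.finite(v) | v <= 0, paste0("nonpositive or missing ", col))
  }
  bad_row(records$noc_true < 1L | records$noc_assumed < 1L,
          "contributor numbers must be positive")
  tmpl_ok <- vapply(records$contributor_templates, function(t) {
    length(t) > 0 && all(is.finite(t)) && all(t > 0)
  }, logical(1))
  bad_row(!tmpl_ok, "contributor_templates must be non-empty and positive")
  under <- records$dataset == "noc_under"
  bad_row(under & records$noc_assumed > records$noc_true,
          "noc_assumed exceeds noc_true")
  bad_row(!under & records$noc_assumed != records$noc_true,
          "noc_assumed must equal noc_true outside noc_under records")
  invisible(records)
}

#' Template of the highest-level contributor (Tc)
#'
#' Tc is the largest per-contributor template (RFU) of an interpretation;
#' plotting only the highest-level contributor avoids skewing trends in
#' favor of mixtures with more contributors.
#'
#' @param x Either a numeric vector of contributor templates or a
#'   `vp_records` data frame (returns one Tc per row).
#' @return Positive numeric: Tc in RFU.
#' @export
#' @examples
#' tc_of(c(100, 4097, 50, 20))  # 4097
tc_of <- function(x) {
  if (is.data.frame(x)) {
    return(vapply(x$contributor_templates, tc_of, numeric(1)))
  }
  x <- as.numeric(x)
  if (length(x) == 0) stop("contributor template list is empty")
  if (any(!is.finite(x) | x <= 0)) stop("templates must be positive and finite")
  max(x)
}

#' Convert records to log-log points for one parameter type
#'
#' Trends in variance parameter versus template span orders of magnitude in
#' both variables, so the working-range analysis is done on base-10 logs:
#' x = log10(Tc), y = log10(variance parameter).
#'
#' @param records A `vp_records` data frame.
#' @param parameter_type One of [vp_parameter_types()].
#' @return A data frame with columns `x`, `y`, `parameter_type` and
#'   `dataset`, one row per record.
#' @export
to_log_points <- function(records, parameter_type) {
  validate_vp_records(records)
  parameter_type <- match.arg(parameter_type, vp_parameter_types())
  col <- vp_var_column(parameter_type)
  data.frame(
    x = log10(tc_of(records)),
    y = log10(records[[col]]),
    parameter_type = parameter_type,
    dataset = records$dataset,
    stringsAsFactors = FALSE
  )
}

#' Read or write interpretation records as CSV
#'
#' The on-disk format is RFC-4180 CSV (UTF-8, mandatory header) with one row
#' per replicate interpretation and contributor templates packed into a
#' single semicolon-separated cell. `read_vp_records` reports malformed rows
#' by line; `write_vp_records` followed by `read_vp_records` is the identity
#' on valid records.
#'
#' @param path CSV file path.
#' @param records A `vp_records` data frame.
#' @return `read_vp_records` returns a `vp_records` data frame;
#'   `write_vp_records` returns `path` invisibly.
#' @export
read_vp_records <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("sample_id", "dataset", "noc_true", "noc_assumed",
                "contributor_templates", "allele_var", "rev_stutter_var",
                "fwd_stutter_var")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("CSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(vp_records(character(0), character(0), integer(0), integer(0),
                      list(), numeric(0), numeric(0), numeric(0)))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad) > 0) {
      stop("unparseable ", col, " at data row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
    v
  }
  templates <- lapply(strsplit(raw$contributor_templates, ";", fixed = TRUE),
                      function(s) suppressWarnings(as.numeric(s)))
  bad_tmpl <- which(vapply(templates,
                           function(t) length(t) == 0 || anyNA(t), logical(1)))
  if (length(bad_tmpl) > 0) {
    stop("unparseable contributor_templates at data row(s): ",
         paste(utils::head(bad_tmpl, 10L), collapse = ", "))
  }
  vp_records(raw$sample_id, raw$dataset, num("noc_true"), num("noc_assumed"),
             templates, num("allele_var"), num("rev_stutter_var"),
             num("fwd_stutter_var"))
}

#' @rdname read_vp_records
#' @export
write_vp_records <- function(records, path) {
  validate_vp_records(records)
  out <- as.data.frame(records[, c("sample_id", "dataset", "noc_true",
                                   "noc_assumed")], stringsAsFactors = FALSE)
  out$contributor_templates <- vapply(
    records$contributor_templates,
    function(t) paste(format(t, digits = 15, trim = TRUE, scientific = FALSE),
                      collapse = ";"),
    character(1))
  for (col in c("allele_var", "rev_stutter_var", "fwd_stutter_var")) {
    out[[col]] <- records[[col]]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.vp_records <- function(x, ...) {
  cat("Interpretation records:", nrow(x), "rows\n")
  tab <- table(factor(x$dataset, levels = vp_dataset_labels()))
  tab <- tab[tab > 0]
  if (length(tab) > 0) {
    cat("  datasets:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
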