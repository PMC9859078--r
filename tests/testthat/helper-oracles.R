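# Independent oracles and fixture builders used across the suite.

# Brute-force polynomial OLS via explicit normal equations: deliberately
# naive (no QR), serving as an independent cross-check of the fitting path.
ne_poly_fit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Quartic coefficients of the shipped reference calibration (b0..b4),
# used to build noiseless recovery fixtures.
ref_coefs <- function(parameter_type = "allele") {
  unname(coef(reference_calibration()[[parameter_type]]))
}

# Direct (non-Horner) polynomial evaluation.
poly_eval <- function(b, x) {
  drop(outer(x, seq_along(b) - 1, `^`) %*% b)
}

# One hand-built valid record.
make_record <- function(sample_id = "s1", dataset = "unchallenged",
                        templates = c(1500, 300), allele = 3.1,
                        rev = 6.2, fwd = 4.9, noc_true = length(templates),
                        noc_assumed = noc_true) {
  vp_records(sample_id, dataset, noc_true, noc_assumed, list(templates),
             allele, rev, fwd)
}

# Random valid records for property tests.
random_records <- function(n, seed) {
  set.seed(seed)
  noc <- sample(1:4, n, replace = TRUE)
  templates <- lapply(noc, function(k) round(10^runif(k, 1.5, 4.2), 3))
  vp_records(
    sample_id = sprintf("r%03d", seq_len(n)),
    dataset = sample(c("unchallenged", "inhibited", "degraded"), n,
                     replace = TRUE),
    noc_true = noc, noc_assumed = noc,
    contributor_templates = templates,
    allele_var = round(10^runif(n, -0.5, 1.2), 6),
    rev_stutter_var = round(10^runif(n, 0, 1.5), 6),
    fwd_stutter_var = round(10^runif(n, 0, 1.5), 6)
  )
}
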