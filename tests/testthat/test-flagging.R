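ref <- reference_calibration()

test_that("ties with a benchmark line never flag (strict inequality)", {
  upper3 <- predict(ref$allele, 3, what = "upper", warn_extrapolation = FALSE)
  rec <- make_record(templates = 1000, allele = 10^upper3, noc_true = 1)
  fl <- flag_records(rec, ref)
  a <- fl[fl$parameter_type == "allele", ]
  expect_false(a$exceeds_empirical_99)
  expect_true(a$exceeds_regression)  # above the trend, on the band
})

test_that("flags are Tc-dependent: the same variance can flip", {
  # threshold at log10(Tc) = 3 is 0.5593 + 0.2156 = 0.7749
  rec_lo <- make_record(templates = 1000, allele = 10^0.80, noc_true = 1)
  fl_lo <- flag_records(rec_lo, ref)
  expect_true(fl_lo[fl_lo$parameter_type == "allele",
                    "exceeds_empirical_99"])
  # at log10(Tc) = 4 the band is higher (~0.9604) and the flag clears
  rec_hi <- make_record(templates = 10000, allele = 10^0.80, noc_true = 1)
  fl_hi <- flag_records(rec_hi, ref)
  expect_false(fl_hi[fl_hi$parameter_type == "allele",
                     "exceeds_empirical_99"])
})

test_that("missing calibrations or priors are named errors", {
  rec <- make_record()
  expect_error(flag_records(rec, ref[c("allele", "reverse_stutter")]),
               "forward_stutter")
  expect_error(flag_records(rec, ref,
                            priors = default_priors()[c("allele")]),
               "reverse_stutter")
})

test_that("flag implications hold on randomized records", {
  rec <- random_records(150, seed = 13)
  fl <- flag_records(rec, ref)
  expect_true(all(!fl$exceeds_empirical_99 | fl$exceeds_regression))
  ok <- !is.na(fl$exceeds_prior_mode)
  expect_true(all(!fl$exceeds_prior_99[ok] | fl$exceeds_prior_mode[ok]))
})

test_that("raising a variance parameter never clears a flag", {
  set.seed(19)
  for (i in 1:20) {
    rec <- random_records(1, seed = 100 + i)
    fl1 <- flag_records(rec, ref)
    rec2 <- rec
    col <- sample(c("allele_var", "rev_stutter_var", "fwd_stutter_var"), 1)
    rec2[[col]] <- rec2[[col]] * runif(1, 1, 50)
    fl2 <- flag_records(rec2, ref)
    flag_cols <- c("exceeds_regression", "exceeds_empirical_99",
                   "exceeds_prior_mode", "exceeds_prior_99")
    for (fc in flag_cols) {
      expect_true(all(fl2[[fc]] >= fl1[[fc]], na.rm = TRUE))
    }
  }
})

test_that("records outside the calibration range are marked extrapolated", {
  rec <- make_record(templates = 10^4.8, noc_true = 1)
  fl <- suppressMessages(flag_records(rec, ref))
  expect_true(all(fl$extrapolated))
  rec_in <- make_record(templates = 1000, noc_true = 1)
  expect_true(all(!flag_records(rec_in, ref)$extrapolated))
})

test_that("exceedance summary computes percentages with counts", {
  # records epsilon above the regression line but below all upper bands
  x <- c(2, 2.5, 3, 3.5)
  mk <- function(eps) {
    vp_records(sprintf("s%d", seq_along(x)), "unchallenged",
               1, 1, as.list(10^x),
               allele_var = 10^(predict(ref$allele, x,
                                        warn_extrapolation = FALSE) + eps),
               rev_stutter_var = 10^(predict(ref$reverse_stutter, x,
                                             warn_extrapolation = FALSE) + eps),
               fwd_stutter_var = 10^(predict(ref$forward_stutter, x,
                                             warn_extrapolation = FALSE) + eps))
  }
  sm <- summarize_exceedance(flag_records(mk(1e-6), ref))
  reg <- sm[sm$benchmark == "regression", "unchallenged"]
  expect_equal(reg, rep(100, 3))
  emp <- sm[sm$benchmark == "empirical_99", "unchallenged"]
  expect_equal(emp, rep(0, 3))
  expect_equal(unique(sm$n_unchallenged), 4L)
  # points exactly on the regression line count as not exceeding
  sm0 <- summarize_exceedance(flag_records(mk(0), ref))
  expect_equal(sm0[sm0$benchmark == "regression", "unchallenged"],
               rep(0, 3))
  # within any dataset and parameter, band exceedance <= trend exceedance
  fl <- flag_records(random_records(200, seed = 23), ref)
  sm2 <- summarize_exceedance(fl)
  for (ds in setdiff(names(sm2), c("parameter_type", "benchmark",
                                   grep("^n_", names(sm2), value = TRUE)))) {
    for (pt in vp_parameter_types()) {
      sub <- sm2[sm2$parameter_type == pt, ]
      expect_lte(sub[sub$benchmark == "empirical_99", ds],
                 sub[sub$benchmark == "regression", ds])
    }
  }
})
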