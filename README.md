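# strvarqc

Quality-control diagnostics for the **average variance parameters** printed
on STRmix-style probabilistic-genotyping interpretation reports.

## The problem

Continuous probabilistic genotyping software models STR peak-height
variation with a lognormal distribution whose spread is governed by
per-interpretation variance parameters (one each for alleles, reverse
stutter and forward stutter):

    log10(O / E) ~ N(0, c² / h)

where `O` and `E` are observed and modeled peak heights (RFU), `h` is the
relevant peak height and `c²` is the variance parameter. Analysts assess an
interpretation partly by comparing its average `c²` values to the prior
gamma distributions built during validation — but the prior's mode and 99th
percentile are constant, while in practice the variance parameters drift
systematically with template amount.

`strvarqc` turns that comparison into a calibrated, template-aware working
range. For each variance parameter it regresses

    y = log10(c²)   on   x = log10(Tc)

by ordinary least squares with a fourth-order polynomial, where `Tc` is the
template (RFU) of the highest-level contributor. The fitted trend plus
**2.326 residual standard deviations** is a one-sided empirical
99th-percentile band. Each interpretation is then flagged against four
benchmark lines:

1. the fitted polynomial regression (typical behavior),
2. the empirical 99th-percentile band (elevated),
3. the prior gamma mode, `(α − 1)β` (constant),
4. the prior gamma 99th percentile (constant).

Flags are advisory — a prompt for closer scrutiny of the electropherogram
and genotype weights, never a pass/fail verdict.

The package also ships a synthetic record generator (quartic trend +
homoscedastic normal log-residuals + challenge-specific shifts) so the
whole pipeline is testable without laboratory data, and a small simulator /
maximum-likelihood estimator for the lognormal peak model itself.

## Worked example

```r
library(strvarqc)

# A synthetic study: 1000 unchallenged records to calibrate on,
# plus 200 inhibited records to assess.
rec <- generate_study(c(unchallenged = 1000, inhibited = 200), seed = 11)
res <- run_pipeline(rec)
res$calibrations$reverse_stutter
#> Variance-parameter calibration (reverse_stutter), degree 4 [fitted]
#>   coefficients (b0 = intercept):
#>         b0         b1         b2         b3         b4
#> -12.301000  21.678700 -12.601700   3.079070  -0.267669
#>   residual SD = 0.1169; upper band = trend + 2.326 * SD = +0.2718
#>   calibration range: log10(Tc) in [1.5, 4.19]

res$summary
#> Percentage of variance parameter values exceeding benchmark lines
#>   parameter_type    benchmark unchallenged inhibited
#>           allele   regression       50.50%    71.50%
#>           allele empirical_99        1.50%     1.50%
#>  reverse_stutter   regression       51.90%   100.00%
#>  reverse_stutter empirical_99        0.50%    60.50%
#>  forward_stutter empirical_99        1.20%    12.00%
#>  ...
```

About half of the unchallenged points sit above each trend line and ~1%
above the empirical band — the construction target — while inhibition
pushes a majority of reverse-stutter variances above the band, the
signature of stutter-dropout modeling stress.

Flag a single casework-style interpretation against the calibration:

```r
case <- vp_records("case_001", "other", 2, 2, list(c(6882, 700)),
                   allele_var = 2.9, rev_stutter_var = 12.4,
                   fwd_stutter_var = 5.1)
flag_records(case, res$calibrations)
#>    parameter_type    x     y exceeds_regression exceeds_empirical_99
#> 1          allele 3.84 0.462              FALSE                FALSE
#> 2 reverse_stutter 3.84 1.093              FALSE                FALSE
#> 3 forward_stutter 3.84 0.708               TRUE                 TRUE
```

At `Tc = 6882` RFU only the forward-stutter parameter exceeds its empirical
band; note the reverse-stutter value (`c² ≈ 12.4`) does *not* flag at this
high template even though the same value would flag at a lower `Tc` — the
band is template-dependent by design.

A published reference calibration (coefficients, band offsets, prior gamma
parameters from a completed GlobalFiler / STRmix v2.8 validation) ships as
`reference_calibration()` and `default_priors()` for use without refitting.

A thin command-line wrapper with `generate` / `calibrate` / `flag` /
`summarize` / `plot` / `simulate-peaks` subcommands is installed at
`system.file("cli", "vpqc.R", package = "strvarqc")`.

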