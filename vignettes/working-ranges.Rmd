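---
title: "Calibrated working ranges for genotyping variance parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated working ranges for genotyping variance parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strvarqc)
```

## The model

Continuous probabilistic genotyping software models the ratio of observed
to expected STR peak heights as lognormal:

$$\log_{10}(O/E) \sim N\!\left(0,\; c^2 / h\right),$$

with variance parameter $c^2$ and relevant peak height $h$ (RFU). For
alleles $h$ is the modeled height of the allele itself; for $-1$ stutter it
is commonly the observed height of the parent allele. Because the spread
shrinks with $h$, the per-interpretation *average* variance parameters
drift systematically with template amount, and comparing them only to the
constant mode of their prior gamma distribution is a blunt diagnostic.

`strvarqc` calibrates a template-aware working range. Writing
$x = \log_{10}(T_c)$ — $T_c$ the template of the highest-level contributor,
chosen so mixtures with many contributors do not dominate the plots — and
$y = \log_{10}(c^2)$, the calibration is the ordinary least-squares fit

$$y = b_0 + b_1 x + b_2 x^2 + b_3 x^3 + b_4 x^4 + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

fitted separately for the allele, reverse-stutter and forward-stutter
parameters on unchallenged interpretations. The empirical upper working
limit is the fitted trend plus $z\,\hat\sigma$ with $z = 2.326$, a
one-sided 99th percentile under normal residuals. Two further constant
benchmarks come from the prior gamma: its mode $(\alpha - 1)\beta$ and its
upper quantile (default $p = 0.99$). Residual normality — the assumption
behind the $+z\hat\sigma$ construction — is checked with the Jarque-Bera
test.

### Assumptions

* Quartic trend in log-log space. Degree 4 is the default (the trends are
  distinctly non-monotone across the usual $T_c$ range, with regime
  changes where stutter peaks cross detection thresholds); the `degree`
  argument permits exploration.
* Homoscedastic normal residuals in $\log_{10}$ units. The band offset is
  constant in $x$; no heteroscedastic extension is provided.
* Replicate interpretations of the same amplification are pooled as
  independent points, unweighted. No clustering correction is applied —
  a known limitation: standard errors and CIs are anti-conservative to the
  extent replicates correlate.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `degree` | 4 | polynomial degree of the trend |
| `z` | 2.326 | band multiplier, in residual SDs (log10 units) |
| `p_prior` | 0.99 | prior gamma upper-quantile benchmark |
| `priors` | shipped reference | gamma shape/scale per parameter type |

`z` is fixed at the rounded 2.326 rather than `qnorm(0.99)` = 2.3263…
so that band arithmetic reproduces published working-range offsets exactly
to their printed precision; the difference is ~1e-4 in log10 units.

The prior gamma `beta` is the **scale** parameter. The convention is not
universal; it was pinned by requiring the shipped reference priors'
closed-form modes $(\alpha-1)\beta$ to reproduce their documented values,
and is stated prominently in the documentation because the rate/scale
mix-up is the classic failure mode here.

## Benchmarks and flagging

`flag_records()` evaluates, per record and parameter type, strict
inequalities $y > \text{line}(x)$ against the four lines. Ties count as
*not* exceeding: a conservative choice (a value exactly on a line carries
no evidence of elevation) in the absence of any established tie rule.
Because the empirical lines depend on $x$, the same variance value can
flag at one template level and not another.

Records whose $T_c$ falls outside the calibration range are still
classified but marked `extrapolated`; refusing out-of-range casework would
make the diagnostic useless exactly where it is needed, and prediction
outside the range warns rather than errors for the same reason. Flags are
advisory; no record is ever rejected.

`summarize_exceedance()` tabulates the percentage exceeding each benchmark
per dataset label, with counts. A dataset tracking calibration conditions
should put roughly half its points above the trend lines and ~1% above
the 99th-percentile lines.

## Numerical choices

* Fitting uses `stats::lm` (QR); the test suite cross-checks coefficients
  against an explicit normal-equations solve to 1e-8 on small instances.
  A warning fires when the raw-polynomial design's condition number is
  extreme; fewer than `degree + 1` distinct $x$ values is an error.
* $\hat\sigma$ uses the unbiased $n - (d{+}1)$ denominator. Published
  offsets do not state their denominator; at calibration sample sizes in
  the thousands the difference is far below the printed precision.
* Polynomial prediction uses Horner evaluation.
* Jarque-Bera uses the classic moment-estimator form
  $JB = \tfrac{n}{6}\left(S^2 + (K-3)^2/4\right)$ with biased ($1/n$)
  central moments and an asymptotic $\chi^2_2$ p-value — the convention of
  spreadsheet-era regression practice. Inputs of length $\ge 3$ with
  nonzero variance are accepted; small-sample Monte-Carlo p-values are out
  of scope.
* A constant response is a degenerate but legal input: coefficients reduce
  to the intercept, $\hat\sigma = 0$, and $R^2$ is reported as 0 with a
  warning (total variance is zero).
* Gamma quantiles use `stats::qgamma` (inverse regularized incomplete
  gamma), never sampling; tests round-trip against `pgamma`. When the
  shape is $\le 1$ the mode is 0, its log10 line is undefined, and
  mode-based flagging is disabled with a warning.
* 99% coefficient confidence intervals are per-coefficient Student-t
  intervals, not simultaneous bands.

## The synthetic generator

`generate_records()` emulates the *statistical structure the analysis
assumes*, at the diagnostic-summary level: $\log_{10}(T_c)$ is drawn
uniformly on `tc_log10_range` (default [1.5, 4.2], spanning the template
range of the reference validation; log-uniform $T_c$ gives even coverage
of the regression domain rather than copying any dilution ladder), and
each parameter's $y$ is the reference quartic trend plus a
challenge-specific shift plus $N(0, \sigma^2)$ noise, independently across
the three parameters per record (no cross-correlations are modeled — a
documented simplification).

The default challenge shifts encode the characteristic directions of the
challenge conditions: inhibition elevates reverse stutter most while
leaving allele variance nearly unchanged; contributor-number
underestimation and cell-line mixtures elevate allele variance most;
degradation moderately elevates allele and reverse stutter; signal
saturation elevates all three, reverse stutter the most. Magnitudes were
set once by one-sided normal tail arithmetic,
$\text{shift} = \sigma\,(2.326 - \Phi^{-1}(1 - p_{\text{exceed}}))$,
from representative published exceedance rates; only the *directions and
orderings* are a generator target — exact exceedance percentages depend on
real laboratory data and are deliberately not reproduced.

What passing tests on this generator shows: the pipeline's arithmetic,
band construction, flagging logic and summaries are correct under the
model's own assumptions. What it does not show: robustness to
heteroscedastic residuals, correlated replicates, cross-correlated
parameters, non-uniform $T_c$ designs, or any electropherogram-level
artifact — none of which the generator emulates.

## Problem sizes

The test suite fits calibrations at $n$ = 300–2000, uses 200-replicate
seeded loops for coverage and normality-rate properties, 5000 peak pairs
for maximum-likelihood recovery, and a 3500-record six-condition study for
the end-to-end ordering checks; these sizes give binomial/chi-square
sampling error comfortably inside the asserted bounds. The acceptance
script uses the same sizes.

## Known limitations

* The shipped reference calibration carries coefficients, band offsets and
  the assumed $x$ range only; its inference fields (R², F, CIs,
  Jarque-Bera) are `NA` because the underlying raw validation data are not
  redistributable, and refitting them is a non-goal.
* No lower working limit is implemented: the genotyping software already
  enforces a floor at half the prior mode, so the upper range is the
  actionable side.
* The shifted-lognormal composite model for coincident allele+stutter
  peaks is out of scope; the peak model implements the single-peak form
  only.
* Parsing vendor report files is out of scope; users export the tabular
  values (the documented CSV dialect) themselves.
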