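Package: strvarqc
Title: Empirical Working Ranges for Probabilistic Genotyping Variance Parameters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quality-control diagnostics for the average variance parameters
    (allele, reverse stutter, forward stutter) reported by continuous
    probabilistic genotyping software such as STRmix. Calibrates empirical
    working ranges by fourth-order polynomial regression of log10(variance
    parameter) on log10(Tc), the template of the highest-level contributor,
    with Jarque-Bera residual diagnostics and a one-sided 99th-percentile
    band; computes constant benchmarks (mode and quantiles) from the prior
    gamma distributions; flags individual interpretations against four
    benchmark lines; and summarizes exceedance rates per challenge dataset.
    Includes a lognormal peak-height variance model and a synthetic
    interpretation-record generator for validation without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
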