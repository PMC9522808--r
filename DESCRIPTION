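Package: zipTreeScan
Title: Tree-Based Scan Statistics for Zero-Inflated Adverse Event Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal detection for hierarchically coded adverse-event (AE)
    count data from spontaneous reporting systems. Implements the classic
    tree-based (Poisson/multinomial) scan statistic and a zero-inflated
    Poisson (ZIP) variant that models structural ("true") zeros via an
    expectation-maximization algorithm, together with Monte Carlo hypothesis
    testing on the maximum likelihood ratio over all candidate cuts of the
    hierarchy, tabular signal reports, and a simulation framework measuring
    type-I error, power, sensitivity and positive predictive value.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), optparse, withr, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
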