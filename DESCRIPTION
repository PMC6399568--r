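Package: mslrt
Title: Likelihood Ratio Test Methods for Safety Signal Detection from
    Multiple Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signal detection for drug safety data collected across several
    clinical or observational studies. Implements the regular likelihood
    ratio test (LRT) for Poisson event rates with exposure denominators,
    its Monte-Carlo empirical null, and three multi-study combiners: the
    simple pooled LRT, the maximum-over-studies statistic (MMLR), and the
    exposure-weighted LRT (wLRn), each with rank-based p-values and
    step-down identification of secondary signals.  Also provides the
    traditional fixed-effect and DerSimonian-Laird random-effects
    meta-analysis of log relative risks used as a comparator, and a
    simulation harness that estimates type-I error and power of all
    methods on conditioned multinomial study grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    metafor,
    jsonlite,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
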