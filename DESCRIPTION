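Package: radxo
Title: Sex-Specific Crossover Rates and Interference from RAD Tags in
    Outbred F1 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates and compares female and male crossover (CO) rates and
    CO interference between the two parents of an outbred F1 population from
    dual-segregation SNP pairs on RAD tags. Pairs of SNPs segregating ab x aa
    (female-informative) and aa x ab (male-informative) on the same tag act as
    two pseudo-testcross datasets over the same genomic intervals. Provides
    multinomial maximum-likelihood estimators and likelihood-ratio tests for
    interval-wise rate differences, three-point coefficient-of-coincidence
    (CoC) estimation with linkage-phase resolution, a minimum-interval-length
    scan for positive and negative interference, gamma-renewal
    interference-strength fitting per chromosome and parent, and a meiosis
    simulator with known rates, phases and interference for validation by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
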