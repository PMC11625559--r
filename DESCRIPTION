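Package: netmr
Title: Two-Sample, Multivariable and Network Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A causal-inference toolkit for genome-wide association (GWAS)
    summary statistics: instrument selection (association, minor-allele
    frequency, F-statistic and linkage-disequilibrium clumping filters, with a
    confounder screen and outcome-overlap exclusion), allele harmonization
    including the palindromic-variant frequency rule, the two-sample Mendelian
    randomization estimator suite (inverse-variance weighted, maximum
    likelihood, MR-Egger, weighted median, simple and weighted mode) with
    Cochran's Q, Egger-intercept, leave-one-out and MR-PRESSO sensitivity
    analyses, multivariable MR with Lasso pleiotropy penalization, network-MR
    mediation by the product-of-coefficients method with Delta-method
    confidence intervals, and a simplified LD-score regression for heritability
    and genetic correlation. A seeded generator of synthetic GWAS summary
    statistics with configurable causal structure, pleiotropy and LD blocks
    makes the whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
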