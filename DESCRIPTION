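Package: stratpower
Title: Odds-Ratio Dilution and Exact Fisher Power for HLA-Stratified
    Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies why a T cell receptor (TCR) susceptibility allele
    whose effect is contingent on a particular HLA class II diplotype is
    nearly invisible to unstratified case-control association analysis.
    Implements the linear odds-ratio dilution model relating a
    stratum-specific odds ratio to the whole-cohort odds ratio and its
    inversion, an exact power engine for Fisher's exact test on two
    independent binomial samples, linkage-disequilibrium (r-squared) power
    attenuation via effective sample size, a seedable synthetic cohort
    generator for empirical validation of the analytic results, and a
    catalog of germline TRAV/TRBV interface polymorphisms with counting
    utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
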