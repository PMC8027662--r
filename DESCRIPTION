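Package: mrselect
Title: Selection Bias in Two-Sample Summary-Data Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and Monte-Carlo engines for studying how
    genome-wide-significance instrument selection distorts two-sample
    summary-data Mendelian randomization. Implements the SMR Wald-ratio
    test and its harmonic-mean decomposition, the min-test and a more
    powerful conditional test of the outcome association with gene-level
    Bonferroni correction, the two-sample MR Steiger directionality test
    on the Fisher-Z scale, and a truncated-normal conditional
    likelihood-ratio remedy for the winner's curse. Includes simulators
    for selection on noncentral chi-square Wald statistics, Wald-ratio
    tail behaviour, Fisher-Z selection experiments, and a synthetic
    cis-eQTL pipeline (Hardy-Weinberg genotypes with AR(1) linkage
    disequilibrium, additive expression models at specified
    heritability) for null-calibration studies, plus readers and writers
    for GCTA-COJO style summary-statistics tables and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
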