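Package: sweepexpress
Title: Selection-Signature Scans and Their Link to Tissue Expression and
    cis-eQTL
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for detecting recent incomplete selective
    sweeps in phased genotype data and relating them to regulatory
    variation. Implements extended haplotype homozygosity (EHH), integrated
    EHH and the standardized integrated haplotype score (iHS), two-step
    peak calling with a top-0.01 percent validation threshold,
    cross-population signature intersection and 50-kb region grouping,
    multi-population Weir-Cockerham FST, windowed LD r2 summaries,
    one-vs-rest moderated-t tissue overexpression ranking with chi-squared
    enrichment, circular-permutation interval-overlap tests, and
    adaptive-eQTL statistics (Spearman correlation of allele-frequency
    differentiation with cis-eQTL effect size, Wilcoxon comparison of
    adaptive versus non-adaptive variants). Includes a forward
    Wright-Fisher simulator with sweep injection and Balding-Nichols
    population divergence to generate inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
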