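Package: popgenpipe
Title: Population-Genomic Inference from SNP Panels: FST, LD-Based Ne,
    Divergence Times and Cross-Population Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for multi-population diploid SNP panels:
    genotype input/output (PLINK binary and VCF), genetic-map
    interpolation and dataset merging; sample and variant quality control
    (missingness, minor allele frequency, exact Hardy-Weinberg test,
    window-based LD pruning, KING-robust kinship and relative removal);
    Weir-Cockerham fixation-index estimation per locus and genome-wide
    with empirical per-SNP p-values; effective-population-size histories
    from linkage-disequilibrium r-squared within sliding
    recombination-distance categories, summarised as a harmonic-mean
    long-term Ne with confidence intervals; pairwise divergence-time
    estimation from FST and Ne with an ultrametric UPGMA tree; a
    cross-population extended-haplotype-homozygosity (XP-EHH) selection
    scan with a joint XP-EHH/FST candidate-region caller; and a forward
    Wright-Fisher simulator with recombination, population splits and
    hard selective sweeps that provides ground-truthed synthetic panels
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
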