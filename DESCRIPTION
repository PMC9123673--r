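Package: xoverscan
Title: Pedigree-Based Analysis of Individual Meiotic Recombination Rate
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to measure and analyse individual recombination rate from
    SNP genotypes and pedigree data in livestock-style populations. Builds
    three-generation full-sib families around focal parents, phases focal
    genotypes by Mendelian rules, counts crossovers in each transmitted gamete
    (autosomal crossover count, ACC), assembles sex-specific Haldane linkage
    maps and cM/Mb recombination landscapes, estimates the heritability of ACC
    with an average-information REML repeatability animal model on the pedigree
    relationship matrix, and runs a mixed-model genome-wide association scan
    with a sparsified genomic relationship matrix and per-SNP variance
    explained. A gamete and pedigree simulator with crossover interference and
    planted trait loci provides fully known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
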