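Package: xomap
Title: Crossover Landscape Analysis for Whole-Genome F2 Genotyping Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse meiotic crossover landscapes from diagnostic-SNP
    parent-of-origin tracks in F2 whole-genome genotyping designs, as used in
    Drosophila recombination mapping. Calls crossovers from origin-block
    switches, builds genetic maps and windowed cM/Mb rate tracks, quantifies
    centromere and telomere effects (proximal-third permutation test and a
    sliding-window extent estimator with crossover-count subsampling),
    measures crossover interference from inter-crossover distances with
    data-driven null expectations and gamma shape (nu) estimation, and
    performs Weinstein tetrad analysis including constrained chi-square
    fitting and a crossover-associated meiotic drive (MD_CO) model of biased
    meiosis-II segregation. A forward simulator of female meiosis generates
    synthetic genotype tables with configurable crossover intensity profiles,
    tetrad-level interference, segregation drive and genotyping noise, so
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
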