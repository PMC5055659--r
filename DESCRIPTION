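Package: spliceCons
Title: Conservation-Based Modelling of Cassette Exon Inclusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how evolutionary conservation around cassette
    exon splice sites relates to percent-spliced-in (PSI). Implements
    junction and windowed-average conservation features and the Junc/Avg
    ratio predictor of exon inclusion, classification of exons into
    conservation regimes (Old-, Old+, New), discovery of intronic splicing
    regulatory elements (ISEs/ISSs) from residual PSI with Mann-Whitney
    tests and Benjamini-Hochberg FDR control, and k-mer conservation
    statistics (conservation enrichment, enrichment bias, ISE/ISS character)
    with a permutation meta-correlation test. Includes a synthetic data
    generator with planted conservation regimes, regulatory motifs and a
    GC-composition confound so that every stage of the analysis can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
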