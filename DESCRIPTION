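Package: plastizymr
Title: Screening for Plastic-Degrading Enzymes in Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects candidate plastic-degrading enzymes (plastizymes) in
    protein, contig or genome input by combining per-polymer profile hidden
    Markov model searches with calibrated E-values, a pairwise-alignment
    fallback search, mean-pooled protein embeddings feeding per-polymer
    classifiers (a precision-oriented gradient-boosted mode and a
    recall-oriented shallow neural-network mode), and read-based gene
    abundance normalization (CPM, RPKM, TPM).  Ships deterministic
    synthetic-data generators (seed families, planted metagenomes, tiled
    reads with known depth) and evaluation utilities (precision, recall,
    F1, MCC, bootstrap confidence intervals, KO-style benchmarking).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    Rsamtools,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
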