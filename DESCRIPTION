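Package: snfgcn
Title: Multi-Omics Patient Classification via Similarity Network Fusion
    and Dense Graph Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates RNA-seq, DNA methylation and copy-number profiles
    into a patient similarity network by iterative similarity network
    fusion, compresses each omic with a denoising autoencoder, and
    classifies patients (e.g. tumor versus normal) transductively with a
    densely connected graph convolutional network.  Includes the full
    preprocessing chain (missingness filtering, sample intersection, mean
    imputation, min-max normalization), stratified train/validation/test
    splitting, classification metrics with rank-based AUC, ablation
    drivers (identity adjacency, omic subsets), and a multi-view
    synthetic-data generator with known latent class structure for
    end-to-end validation.
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
    pROC
Config/testthat/edition: 3
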