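Package: balchimera
Title: Donor-Recipient Chimerism from Sex-Mismatched Droplet scRNA-seq
Version: 0.1.0
Authors@R:
    person("BAL", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of donor versus recipient origin of airway
    macrophages in bronchoalveolar lavage (BAL) single-cell RNA-seq from
    sex-mismatched lung transplants. Provides a droplet-experiment simulator
    with known ground truth, cell-barcode and UMI error correction,
    expected-cell-count based cell calling, MAD and hard-threshold quality
    filtering, library-size log-normalization with PCA and modularity
    clustering, XIST/RPS4Y1 based per-cell sex and origin assignment with
    per-sample chimerism summaries, and exact nonparametric tests
    (Mann-Whitney U, Spearman rank correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
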