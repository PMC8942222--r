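Package: thrombocompare
Title: Comparative Transcriptomics of Young and Mature Zebrafish Thrombocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparing gene expression between
    two sorted cell populations from transcript-level quantification output:
    transcript TPM computation and gene-level aggregation, classification of
    expressed (TPM > 1) and highly expressed (z-score of log TPM > 1.5) genes,
    five-interval TPM binning, duplicate-aware gene-list set algebra with
    cross-species ortholog collapsing, expression-decile overlap mapping,
    k-means heat-map preprocessing, and a seeded zero-inflated expression
    simulator that emulates the statistical structure of young (RFP+) and
    mature (GFP+) zebrafish thrombocyte single-cell RNA-seq data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
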