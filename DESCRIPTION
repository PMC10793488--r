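Package: neumo
Title: Quantifying Neutrophil-Like Monocyte Transcriptional States in Myeloid Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying a neutrophil-like monocyte (NeuMo)
    transcriptional state in myeloid-derived suppressor cells and monocytes
    from bulk and single-cell RNA-seq. Implements the glucocorticoid
    (dexamethasone) attenuation ratio statistic with a resampling null
    distribution, preranked gene-set enrichment with leading-edge consensus
    metagene construction and sample scoring, guide-matrix constrained
    (semi-supervised) non-negative matrix factorization for Neu-like/DC-like
    state deconvolution, inverse-variance meta-analytic pooling of score
    differences, overlap-coefficient integration of gene-set collections, and
    clustering-stability resolution selection via the adjusted Rand index.
    Synthetic-data generators with known ground truth make the whole pipeline
    testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    igraph,
    mclust,
    metafor,
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
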