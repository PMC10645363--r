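Package: cloneCNA
Title: Joint Copy-Number Clone Inference from Single-Cell RNA and ATAC Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers copy-number clones from single-cell RNA-seq and ATAC-seq
    counts mapped to genomic segments. Cells are clustered with a Dirichlet
    mixture of Negative Binomials whose means scale linearly with the latent
    integer copy number of each segment; the two modalities are linked through
    a shared copy-number probability tensor and balanced by a shrinkage weight.
    Parameters are learnt by stochastic gradient variational inference with a
    Gumbel-Softmax relaxation of the categorical copy-number states, and the
    number of clones is selected by BIC, AIC or ICL. Includes a clone-tree
    count simulator and an evaluation suite (adjusted Rand index, copy-number
    mean absolute error with optimal cluster matching).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    GenomicRanges,
    IRanges,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
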