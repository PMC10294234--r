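Package: tkiclonal
Title: Clonal Evolution Analysis of TKI-Resistant CML Cell-Line Sublines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracks clonal evolution in tyrosine kinase inhibitor (TKI)
    resistance models of chronic myeloid leukemia from serial exome variant
    calls. Implements a staged variant-allele-frequency (VAF) filter cascade
    across sensitive, low-dose and high-dose resistant sublines with
    trajectory classification, driver-gene catalogue intersection and
    oncoplot construction, 96-channel trinucleotide mutational-signature
    decomposition by non-negative least squares, and heat-diffusion network
    propagation of mutated genes over protein-protein interaction graphs
    with subline and gene-set clustering. A synthetic-data module generates
    reference, exon, VCF, signature, catalogue, network and gene-set inputs
    with known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    igraph,
    Matrix,
    pracma,
    cluster,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
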