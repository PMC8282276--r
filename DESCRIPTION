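Package: lvbioage
Title: Biological-Age Transcriptomics of the Human Left Ventricle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the biological age of left-ventricle tissue
    from bulk transcriptomes and for dissecting its microRNA regulation.
    Implements two transcriptomic age markers (CDKN2A senescence-gene
    expression and AppAge, a precision-weighted transcriptional age index
    calibrated from age-related genes), whole-transcriptome hierarchical
    clustering with kernel-density overlap statistics, automatic fibrosis
    quantification from H&E histology via stain deconvolution, young-versus-old
    differential expression with pre-ranked gene set enrichment, identification
    of biological-age-related miRNAs and their mirror-expressed targets, a
    bipartite miRNA-gene regulatory network builder, and the SPM tissue
    specificity score. A synthetic-cohort generator with known ground truth
    (latent biological ages, planted age genes and miRNAs, regulatory edges,
    histology masks) supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
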