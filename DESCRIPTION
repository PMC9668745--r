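Package: spermchrom
Title: Quantifying Histone-Variant-Driven Sperm Chromatin Condensation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An analysis pipeline for studying how a sperm-specific histone
    H2B variant condenses transcriptionally inactive, AT-rich chromatin.
    Provides window-level ChIP enrichment (log2 IP/input) with a four-stage
    peak caller, bisulfite window methylation, chromatin-state classification
    of transposable elements by H3K9me2 bimodality, correlation/PCA and
    incremental multivariate regression of enrichment against transcription
    and GC content, Hi-C contact-matrix distance decay and genotype
    comparison with quantile-pair coupling analysis, 3D nuclear image
    segmentation and foci volumetry, and the classical group statistics used
    throughout. A synthetic-data module generates genomes, coverage tracks,
    contact matrices and image stacks with planted, recoverable parameters so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    tiff,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
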