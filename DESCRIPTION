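Package: ambiscore
Title: Contamination-Focused Quality Metrics for Unfiltered Droplet scRNA-seq
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores unfiltered droplet single-cell RNA-seq count matrices on a
    continuous ambient-RNA contamination scale, before any barcode filtering.
    Implements geometric metrics on the normalized cumulative transcript-count
    curve (secant-line distances, inverted AUC percentage), a statistical
    metric from the scaled slope distribution of that curve, ambient-gene
    identification by dropout rate, standard per-cell QC metrics, and a
    PCA-weighted overall contamination score. Includes a droplet simulator
    with controllable ambient contamination for calibration and validation,
    depth downsampling, Matrix Market I/O, and single-sample and cohort
    pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    rhdf5
Config/testthat/edition: 3
biocViews: SingleCell, QualityControl, Transcriptomics
RoxygenNote: 7.3.3
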