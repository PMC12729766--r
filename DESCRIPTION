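Package: screpair
Title: Transcriptome Repair of Degraded RNA-Seq Expression Profiles
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates technical degradation of single-cell and bulk RNA-seq
    expression profiles (3'-end coverage bias, gene dropout, additive
    technical noise) and repairs degraded profiles with a one-step
    conditional Transformer network trained to invert the degradation map.
    Includes a Splatter-style synthetic data generator with planted cell
    types and marker genes, a 10x-style Matrix Market / CSV reader and
    writer, the standard QC / counts-per-10k / log1p / highly-variable-gene
    preprocessing pipeline, MLP denoising and variational autoencoder
    baselines, deterministic train/validation/test splitting with a
    reduce-on-plateau learning-rate schedule, and a technical plus
    biological evaluation scorecard (MSE, Pearson, PR-AUC, F1, silhouette
    cell-type separation, differential-expression preservation, marker-gene
    recovery) with paired significance testing and orthogonal RNA-protein
    validation against a paired surface-protein panel.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    cluster,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
biocViews: SingleCell, Transcriptomics, Preprocessing, QualityControl,
    GeneExpression
Config/testthat/edition: 3
RoxygenNote: 7.3.3
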