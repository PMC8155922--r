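Package: mrsport
Title: Voxel-Wise MR-Spectroscopy Lesion Characterization and Glioma Subtype Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of 2D chemical-shift-imaging (CSI) proton MR spectroscopy
    for brain-lesion characterization. Provides a synthetic CSI phantom and
    cohort generator with known ground truth, spectral baseline correction and
    linear basis-set metabolite quantitation, residual-based quality filtering,
    min-max normalization, a mirrored sigmoid autoencoder for denoising
    metabolite matrices with eigenvalue-benchmark bottleneck selection,
    PCA with parallel-analysis selection of non-trivial components,
    shared-nearest-neighbor clustering and UMAP embedding with marker-metabolite
    enrichment, and a two-layer multiclass Fisher linear discriminant model that
    predicts lesion class per voxel and the glioma molecular subtype
    (IDH-wildtype, IDH-mutant, IDH-mutant with 1p/19q codeletion) per patient
    via a calibrated classifier score.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    pracma,
    igraph,
    FNN,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
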