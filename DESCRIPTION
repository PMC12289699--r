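Package: srcradiomics
Title: Regional Radiomics and Sparse-Representation Classification for
    Multimodal Brain MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for atlas-based regional radiomics of multimodal 3-D
    brain MRI and sparse-representation classification of diagnostic groups.
    Generates seeded synthetic multimodal cohorts with a voxel-aligned
    cerebellar-style parcellation, computes a 57-feature catalogue per region
    and modality (18 intensity-histogram features and 39 texture features from
    gray-level co-occurrence, run-length, size-zone and neighborhood
    gray-tone difference matrices), screens features by sparse coding of the
    class indicator, classifies by minimum class-restricted reconstruction
    residual with an orthogonal matching pursuit solver, and evaluates with
    stratified cross-validation/test splits, confusion-matrix metrics and
    ROC/AUC reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
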