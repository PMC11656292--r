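Package: anatrobust
Title: Anatomy-Aware Robust Optimization for Intensity-Modulated Proton Therapy at Phantom Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates longitudinal head-and-neck phantoms with progressive
    interfractional anatomy change (target and salivary-gland shrinkage, medial
    parotid drift, neck contraction, small nonrigid variations), builds a
    population average weekly deformation model, optimizes proton pencil-beam
    spot weights with a minimax robust objective under combined anatomy, setup
    and range uncertainty, and evaluates treatment courses by deformable dose
    accumulation: voxel-wise minimum/maximum dose, DVH metrics (V94, D2%,
    D0.03cc, Dmean), logistic NTCP models for xerostomia and dysphagia, gamma
    analysis, and paired Wilcoxon comparisons between planning strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
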