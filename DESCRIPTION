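Package: hacsurf
Title: Surface Descriptors and Interpretable Classification of Highly
    Abundant Cytoplasmic Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts physicochemical, structural and geometrical
    descriptors from the solvent-accessible and solvent-excluded surfaces
    of predicted protein structures (AlphaFold-style PDB files carrying
    per-residue pLDDT in the B-factor column) and uses them to classify
    highly abundant cytoplasmic (HAC) versus extracellular proteins with
    an interpretable logistic model.  Includes a deterministic
    Shrake-Rupley solvent-accessible surface area implementation, a
    voxel-grid solvent-excluded surface estimator with a fractal-dimension
    roughness descriptor, a simplified Kabsch-Sander secondary-structure
    assignment, pLDDT-derived pseudo-B-factors, Henderson-Hasselbalch net
    surface charge, Pearson/collinearity screening, Cook's-distance
    outlier removal, repeated stratified model comparison (KNN, random
    forest, SVM, logistic regression) and Wald odds-ratio inference, plus
    synthetic structure and feature-table generators so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    MASS,
    e1071,
    randomForest,
    class,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
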