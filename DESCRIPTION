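Package: morphancestry
Title: Genetic and Phenotypic Ancestry Correction for Dense 3D Facial Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ancestry effects in dense quasi-landmark
    representations of the human face. Implements symmetrization and
    generalized Procrustes superimposition of landmark configurations,
    partial least squares regression (PLSR) correction for covariates and
    genetic ancestry principal components, permutation tests of the shape
    variance explained by predictor sets, regional consensus-face
    construction with (admixture-weighted) consensus correction, and
    per-landmark effect maps (normal displacement, angle difference,
    maximum ancestry shift). A synthetic cohort generator with known
    regional deformations, covariate effects, genetic PC structure and
    admixture proportions makes every stage testable without access to
    restricted facial-scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
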