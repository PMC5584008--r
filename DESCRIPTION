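Package: ecleanse
Title: Electronic Cleansing of Fecal-Tagged CT Colonography Volumes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Electronic cleansing (EC) for CT colonography with positive
    fecal tagging. Implements colonic lumen preprocessing (outside-air,
    lung and bone removal by seeded region growing), detection of thin
    ambiguous layers at the air-tagging interface and their classification
    into artifact (AT) versus genuine air-tissue-tagging (ATT) layers by
    directional connectivity counting, a partial-volume material-fraction
    model based on orthogonal projection onto the arch transition curve,
    the gradient-directional second derivative (GDSD) in Gaussian scale
    space, and the replacement rules that remove tagged material, AT
    layers and T-junction artifacts while preserving submerged soft
    tissue. A parametric digital phantom generator with per-voxel ground
    truth (materials, subvoxel fractions, layer labels) makes the whole
    pipeline testable without clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, RNifti, yaml, jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
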