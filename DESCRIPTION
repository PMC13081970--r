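Package: fibrect
Title: Structure-Tensor Fiber Orientation Mapping and Tractography for 3D
    Tomographic Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts large label-free 3D tomographic volumes (e.g. synchrotron
    phase-contrast scans of brain tissue) into voxel-wise fiber orientations via
    structure tensor analysis, aggregates them into supervoxel fiber Orientation
    Distribution Functions (fODFs) represented by real even-order spherical
    harmonics, computes anisotropy maps (Cl, Cp, Cs, FA, GFA), and performs
    probabilistic streamline tractography driven by the fODF field. Includes
    out-of-core chunked processing with halo padding, gradient-level vessel
    masking with Angular Correlation Coefficient analysis of vascular confounds,
    and a synthetic phantom generator with ground-truth orientation fields for
    validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
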