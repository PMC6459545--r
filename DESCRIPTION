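Package: fibramorph
Title: Morphometric Analysis of Fibrous Biomaterial Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of fibrous structures in 3D tomographic
    volumes of biomaterials such as electrospun scaffolds. Generates
    synthetic fiber phantoms with ground-truth orientation and diameter,
    estimates per-voxel 3D fiber orientation with the second-order structure
    tensor, global 2D orientation from the Fourier power spectrum, local
    fiber diameter by perpendicular ray casting from the medial axis,
    porosity and connected-component morphometrics, orientation colour
    mapping, Tukey post-hoc statistics, and the validation protocols
    (window-size, noise and angular-range sweeps) that characterise the
    estimators against phantom ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    withr,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'fibramorph-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'utils.R'
    'cli.R'
    'diameter.R'
    'evaluate.R'
    'io.R'
    'morpho.R'
    'orient.R'
    'preprocess.R'
    'simulate.R'
    'viz_stats.R'
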