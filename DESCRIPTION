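Package: splenvas
Title: Serial-Section 3D Reconstruction of Splenic Red Pulp Microvasculature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for reconstructing microvascular
    networks from serial brightfield sections of immunostained tissue, built
    around the splenic red pulp use case: Reinhard color normalization,
    sparse global stack registration on the deconvolved blue channel, color
    deconvolution of triple stains (SMA brown, CD34 blue, CD271/CD20 red on
    alternating sections), optical-flow z-interpolation of anisotropic
    volumes, channel-specific grayscale morphology, iso-surface extraction,
    watertight octree mesh repair, Taubin smoothing, quadric decimation,
    proximity-based mesh painting and B-cell pruning, geodesic vessel-path
    measurement, and a synthetic stained-section phantom generator with known
    vascular ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'io.R'
    'mesh_ops.R'
    'meshing.R'
    'phantom.R'
    'pipeline.R'
    'recovery.R'
    'splenvas-package.R'
    'stack_prep.R'
    'stain.R'
    'unmixing.R'
    'utils.R'
    'volume_build.R'
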