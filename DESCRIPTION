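Package: tmsfield
Title: Transcranial Magnetic Stimulation Electric-Field Modelling, Surrogate
    Prediction and Real-Time Streaming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling the electric field induced in the head by
    transcranial magnetic stimulation (TMS). Provides synthetic multi-shell
    spherical head models with anisotropic white-matter conductivity tensors,
    analytic figure-8 coil dA/dt fields, a quasi-static finite-volume solver
    for the induced scalar potential and total E-field, a multi-scale residual
    3D U-Net surrogate for sub-second E-field prediction trained on
    solver-generated cases, vector-aware rigid transforms and resampling for
    volumetric fields, an OpenIGTLink-subset codec and in-process streaming
    loop for coil-pose-in / field-image-out operation, and the timing and
    comparative statistics used to benchmark real-time TMS visualization
    against conventional pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
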