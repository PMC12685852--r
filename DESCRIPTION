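Package: mvquant
Title: Mitral Valve Geometry and Effective Orifice Area from 4D Echocardiographic Label Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies mitral valve geometry from labelled 3D/4D
    transesophageal echocardiography volumes. Reconstructs a volumetric
    annulus segmentation from sparse manual control points (periodic spline
    fit, dense sampling, cylindrical tube voxelization, connected-component
    post-processing), extracts the annulus centerline by 3D morphological
    thinning, fits the valve plane by principal component analysis, projects
    all labelled structures onto the plane, and measures calibrated structure
    areas and the effective orifice area per cardiac frame. Per-frame
    measurements are assembled into an effective-area curve with
    maximum-opening detection, and paired-measurement validation statistics
    (Pearson correlation, Bland-Altman limits of agreement) are provided.
    Also implements the multi-class segmentation objectives used to train
    valve segmentation networks (generalized Dice loss, focal loss, their
    combination, deep supervision with nearest-neighbour downsampled ground
    truth) and the corresponding evaluation metrics. Analytic saddle-annulus
    valve phantoms with known plane, orifice schedule and effective areas
    make every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    splines,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
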