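Package: ecogloc
Title: Automated Localization of Intracranial Electrodes in Post-Implant CT
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects and classifies ElectroCorticoGraphy (ECoG) disc
    electrodes and penetrating depth-electrode contacts in post-implant head
    CT volumes. The pipeline resamples the CT to isotropic 0.5 mm cubic
    voxels with cubic-spline interpolation, thresholds metal radiodensity
    (HU > 2500), labels 6-connected voxel clusters, computes six geometric
    shape descriptors per cluster (volume, the three moment-equivalent
    ellipsoid axis lengths, circularity and cylinder similarity) and
    separates electrodes from wires, stitches and screws with a
    Gaussian-kernel support vector machine, evaluated by stratified tenfold
    cross-validation and cross-dataset transfer. A synthetic CT phantom
    generator with per-object ground truth makes every stage testable
    without patient data. Includes minimal NIfTI-1 and single-series DICOM
    readers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
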