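Package: otls3d
Title: Simulation and Analysis Pipeline for Rapid 3D Light-Sheet Biopsy Pathology
Version: 0.1.0
Authors@R: person("OTLS", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools for simulating and reconstructing open-top light-sheet (OTLS)
    microscopy of prostate needle-core biopsies and for evaluating the rapid
    3D pathology workflow built on it. Provides seeded synthetic biopsy
    phantoms with ground-truthed benign and Gleason-pattern gland morphology,
    a forward model of 45-degree oblique stage-scan acquisition with depth
    attenuation and shot/read noise, shear (deskew) reconstruction into
    calibrated 3D volumes, Sobel-based edge enhancement, a multiresolution
    BigDataViewer-style XML/HDF5 writer and reader, a pipelined multi-biopsy
    workflow timing model, and diagnostic-accuracy plus inter-rater agreement
    statistics (sensitivity, specificity, predictive values, majority vote,
    Randolph's free-marginal multirater kappa with bootstrap confidence
    intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
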