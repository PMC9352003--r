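Package: fujigrade
Title: Machine-Vision and NIR Chemometrics Grading of Red Fuji Apples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end grading toolkit for near-round fruit such as the
    Red Fuji apple. Appearance quality is measured from top-view RGB images
    (surface-defect pixel ratio, contour aspect ratio, maximum
    cross-sectional diameter via image moments and the convex hull) and
    classified against national-standard style thresholds. Internal quality
    (soluble solids, degrees Brix) is predicted from 400-1000 nm diffuse
    reflectance spectra through a chemometrics pipeline: black/white
    reflectance correction, wavelength decimation, multiplicative scatter
    correction and standard normal variate preprocessing, SPXY
    calibration/prediction partitioning, NIPALS partial least squares
    regression, and CARS or SPA characteristic-wavelength selection. A
    comprehensive decision rule combines defect, shape and Brix grades into
    excellent / first-class / second-class / substandard quality grades plus
    a four-level size grade. Synthetic image and spectra generators with
    known ground truth make every stage testable without physical samples.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
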