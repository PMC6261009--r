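Package: limbus3d
Title: Non-Parametric 3D Limbus Detection and Dynamic White-to-White
    Measurement from Anterior-Eye Profilometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects the corneoscleral limbus as a full 360-degree
    three-dimensional contour from anterior-eye surface height data by
    locating, on every meridian, the turning point of the second radial
    derivative of sagittal height, and measures the visible iris boundary
    (white-to-white) from calibrated grayscale eye images by dynamic
    thresholding on the light-intensity frequency spectrum.  Includes
    least-squares plane fitting of the limbus contour with tilt angles,
    sagittal depths, the radial limbus-minus-white-to-white difference
    map, cohort summary statistics with two-sample t-tests, readers and
    writers for profilometer-style records, and synthetic ground-truth
    generators for surfaces and eye images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
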