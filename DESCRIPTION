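Package: lvtdm
Title: Left Ventricular Thrombus Detection Method for Echocardiography
    Cine Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Postprocessing of grayscale echocardiography cine loops for
    left ventricular thrombus assessment. Implements a parameterized
    Reinhard tone-mapping operator applied selectively to an apical
    region of interest, with mild smoothing elsewhere; readers and
    writers for multi-frame ultrasound DICOM, uncompressed AVI and PNG
    sequences; diagnostic-performance statistics for rater studies
    (confusion counts, sensitivity/specificity/predictive values,
    single-operating-point ROC area, and the tie-corrected Friedman
    test); and a seeded synthetic B-mode speckle phantom with ground
    truth masks for method validation without clinical data.
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
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
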