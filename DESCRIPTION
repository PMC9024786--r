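Package: retimetrics
Title: Multimodal Retinal Imaging Biomarkers for Photoreceptor Degeneration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies structural biomarkers of retinitis pigmentosa from
    three retinal imaging modalities: hyperautofluorescent ring diameters on
    fundus autofluorescence, ellipsoid-zone and external-limiting-membrane
    widths plus normalised ellipsoid-zone reflectance from longitudinal
    reflectivity profiles on optical coherence tomography B-scans, and foveal
    cone density plus intact-mosaic diameter on adaptive-optics scanning laser
    ophthalmoscopy.  Includes the agreement and segmented (hinge) regression
    statistics used to relate the modalities, and a synthetic retinal phantom
    generator with per-eye ground truth so that every measurement stage can be
    validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    graphics,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
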