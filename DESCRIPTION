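Package: vertamorph
Title: Landmark-Based Para-Sagittal Plane Morphometry of Vertebral Endplates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs mid-sagittal and quarter para-sagittal reference planes
    on 3D sub-axial cervical vertebra meshes from five named anatomical
    landmarks, extracts the closed sagittal section curves by mesh-plane
    intersection, measures endplate depths (SED, IED) and inferior endplate
    concavity depth (IECD) in each plane, and evaluates intra- and
    inter-observer reliability with normality-routed paired comparisons and
    intraclass correlation coefficients. Includes a parametric synthetic
    vertebra generator with closed-form measurement ground truth and an
    observer-variability study simulator, so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
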