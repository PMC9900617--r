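Package: aaamotion
Title: Landmark-Based Linear Transformation Analysis of Abdominal Aortic
    Aneurysm Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing sequential abdominal aortic aneurysm (AAA)
    imaging through a landmark-based linear transformation. Estimates
    rigid, similarity or affine transformations between paired anatomical
    landmark sets by least squares, gates them with a held-out validation
    point, and projects the points of maximum intraluminal thrombus
    thickness, peak wall stress and peak wall rupture index from the
    earlier study into the later one to measure their spatial motion.
    Includes centerline-based aneurysm morphometry (tortuosity, neck
    angulation, diameters, volumes), an analytic thin-wall surrogate for
    wall stress and rupture index, a synthetic paired-timepoint cohort
    generator with controllable growth and correlation structure, and a
    cohort-level statistical analysis of geometric and biomechanical
    change.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
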