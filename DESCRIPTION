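Package: arteryMech
Title: Biaxial Mechanics and Elastin Band Quantification for Cerebral Arteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of passive biaxial extension-inflation tests on small
    cerebral arteries (thin-wall stress and stretch computation under
    incompressibility, exponential stress-stretch fitting, tangent stiffness,
    and estimation of the in-vivo axial stretch from axial-force invariance),
    together with a grid-based quantification of "empty band" gaps in the
    elastic fiber network of multiphoton wall projections, group summary
    statistics for donor cohorts and relative collagen abundances, and seeded
    synthetic-data generators (inflation forward model, two-layer fiber
    images with a ground-truth gap, cohort and abundance tables) so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
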