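Package: irisMech
Title: In Vivo Iris Biomechanics from Pupillary Light Reflex Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying human iris biomechanics from near-infrared
    video of the pupillary light reflex. Provides a seeded synthetic frame
    generator with closed-form ground-truth kinematics, pupil segmentation and
    Daugman integro-differential limbus localization, subset-based incremental
    digital image correlation with Lagrangian strain fields and radial strain
    profiles, a finite-strain compressible neo-Hookean plane-stress annulus
    model of the iris with an active circumferential sphincter traction ring,
    and multi-start inverse identification of the sphincter
    traction-to-stiffness ratio, its dependence on sphincter width, and the
    associated power-law regression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    png,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
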