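Package: articuvel
Title: Tongue-Tip Velocity from Real-Time and Phase-Contrast Dynamic MRI
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring articulator (tongue-tip) velocity during
    consonant production with two independent dynamic-MRI routes: (i)
    tracking in real-time mid-sagittal magnitude series via
    spatio-temporally regularized deformable registration followed by
    differentiation and projection onto an oblique slice normal, and (ii)
    direct velocity decoding from velocity-encoded (VENC) phase-contrast
    cine series with magnitude-masked region-of-interest averaging.
    Includes simultaneous-audio segmentation and audio-to-MRI alignment,
    kinematic feature-point extraction (stop points, velocity peaks,
    per-phase means) with timing statistics against acoustic landmarks,
    and a seeded synthetic phantom generator (image series, phase images
    and audio with known ground truth) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
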