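Package: refractsim
Title: Virtual Subjective Refraction from Ocular Wavefront Aberrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the retinal image formed by an aberrated schematic eye
    viewed through a virtual phoropter, a Jackson Cross Cylinder (JCC) and/or
    a concentric-ring multifocal contact lens, using Fourier optics on OSA
    standard Zernike aberrometry. On top of the image-formation engine it
    drives automated subjective-refraction workflows (fogging, astigmatic
    clock dial, JCC axis and power search with the circle-of-least-confusion
    rule, sphere refinement), computes objective image-quality metrics
    (Strehl and Visual Strehl ratios), and evaluates multifocal contact-lens
    designs through focus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
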