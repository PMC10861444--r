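Package: opmsim
Title: Vectorial Diffraction Simulation of Oblique Plane Light-Sheet Microscopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts polarization-dependent point spread functions, optical
    transfer functions, noise-aware resolution limits and light efficiency for
    oblique plane microscopy (OPM) and other light-sheet systems. Rays emitted
    by fixed-orientation fluorophore dipoles are traced through a three
    microscope relay as 3x3 polarization (Jones) matrices, including objective
    transmission masks, Fresnel interfaces and the tilted tertiary pupil; the
    focal field is evaluated with an FFT-based Debye integral, passed through a
    Poisson/Gaussian camera noise model, and resolution limits are extracted
    from the first zero crossing of the background-subtracted optical transfer
    function. Includes sweep drivers that compare s- and p-polarized
    light-sheets across inclination angles and photon budgets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
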