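Package: optheart
Title: Born-Normalized Optical Projection Tomography Cartography of the
    Mouse Heart
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, correction, reconstruction and cartography of
    dual-channel transillumination optical projection tomography (OPT)
    data from whole cleared mouse hearts. Provides a synthetic
    left-ventricle phantom with a Beer-Lambert/single-scatter forward
    model, sinogram-domain corrections (source-power equalization,
    ring-artifact removal, denoising), filtered backprojection with
    Born-ratio normalization of fluorescence channels, a thick-walled
    truncated-ellipsoid left-ventricle model in prolate spheroidal
    coordinates, cylindrical and AHA 17-segment Bull's-Eye surface maps,
    bead-based infarct delineation with distance-band probe
    quantification, and translational and rotational cross-correlation
    colocalization analysis of probe pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
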