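Package: oxiring
Title: Automated Retinal Oximetry from Dual-Wavelength Pseudocolor Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic analysis of dual-wavelength retinal oximetry
    pseudocolor exports. Segments the optic disc with a shape-constrained
    active disc (contrast energy minimized by gradient descent with
    Green's-theorem contour gradients, initialized by normalized
    cross-correlation), extracts an optic-disc-centered ring region of
    interest with laterality-aware anatomical quadrants, inverts the
    pseudocolor lookup table to per-pixel oxygen saturation, and estimates
    arteriolar and venular saturation and their difference (AVSD) from the
    two dominant peaks of a degree-twelve polynomial fit to the saturation
    histogram. Includes a ground-truthed synthetic scene generator and the
    method-agreement statistics (intraclass correlation, Bland-Altman)
    used to validate automated against manual readings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
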