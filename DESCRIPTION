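Package: nvcouple
Title: Neurovascular Coupling Analysis of Odor-Evoked Widefield Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured widefield imaging of the
    dorsal olfactory bulb: consistency-thresholded ROI detection of odor-evoked
    blood-volume (intrinsic reflectance) responses, GCaMP6f calcium-to-firing-rate
    deconvolution, gamma-variate neurovascular transfer-function estimation, and
    response-magnitude metrics (AUC, coupling ratio, concentration and age
    regressions). Includes a synthetic-session generator with known ground truth
    (vessel masks, firing rates, true transfer function, photobleach drift and
    noise) so every stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
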