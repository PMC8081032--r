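Package: fusbeam
Title: Backscatter-Based Visualization of Focused Ultrasound Beams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates per-channel radio-frequency data from a linear imaging
    array over synthetic scatterer scenes (speckle backgrounds, circular
    contrast targets, point and wire targets), beamforms focused and steered
    plane-wave transmits by delay-and-sum with dynamic receive aperture and
    coherence-factor weighting, reconstructs the pulse intensity field of a
    focused ultrasound beam, equalizes it by the echogenicity of a coaligned
    plane-wave compounded B-mode image, and evaluates reconstructions with
    beamwidth, depth-of-field, and mean-square-error metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
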