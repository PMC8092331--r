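Package: chromablend
Title: Semi-Synthetic Image Compositing for Surgical Tool Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates semi-synthetic training data for binary surgical
    instrument segmentation by compositing chroma-key-extracted tool
    foregrounds onto tissue backgrounds. Provides HSV + GrabCut foreground
    extraction, a basis of blending functions (trivial copy-paste, Gaussian
    feathering, Laplacian pyramid blending) combined by Dirichlet-weighted
    mix-blend sampling, a domain-randomization augmentation stack (flying
    distractors, endoscopic padding, photometric noise), GrabCut-based
    refinement of network probability maps via certainty bands, and
    IoU/cross-entropy evaluation. Procedural green-screen and tissue
    fixtures make the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    yaml,
    png,
    jpeg,
    tiff,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
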