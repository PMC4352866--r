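Package: v1saliency
Title: Bottom-Up Visual Saliency from Spiking Sparse-Coding V1 Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements a bottom-up visual attention model in which saliency
    is the self-information of the responses of a population of model V1
    neurons. Gabor-like receptive fields are learned from whitened natural
    image patches by a leaky integrate-and-fire spiking network with local
    Hebbian plasticity and lateral inhibition. A colour image is decomposed
    into thirteen channels across four colour spaces (gray, RGB, CIELAB,
    HSI, YIQ); per-channel self-information saliency sub-maps are scored by
    Shannon entropy, the lowest-entropy sub-map is selected from each colour
    space, and the selected maps are fused with reciprocal-entropy weights.
    Includes synthetic fixture generators (1/f noise images, pop-out scenes,
    sparse-dictionary patch sets) and the standard eye-fixation evaluation
    metrics (ROC, AUC, CC, NSS).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
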