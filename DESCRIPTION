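Package: dermrank
Title: Knowledge-Integrated Semisupervised Classification of Dermoscopic
    Lesion Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trains a two-headed convolutional classifier for melanoma
    versus melanocytic nevus that also predicts the three dermoscopic
    features of the 3-point checklist (asymmetry, atypical pigment
    network, blue-white structures).  The diagnostic rule "a higher
    checklist score means a higher melanoma risk" is injected into
    training through a pairwise ranking loss on melanoma logits, and a
    mean-teacher consistency loss lets a large pool of images without
    feature annotations contribute.  Includes the dermoscopic
    preprocessing chain (center crop/resize, Shades of Gray color
    constancy, contrast-limited adaptive histogram equalization on the
    lightness channel), a seeded synthetic lesion generator with
    programmatically embedded checklist features for end-to-end testing
    without clinical images, stratified 5-fold cross-validation, a
    loss-ablation runner, and inter-rater agreement statistics (Cohen's
    kappa, majority-vote adjudication).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    yaml,
    rlang,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    class,
    e1071
Config/testthat/edition: 3
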