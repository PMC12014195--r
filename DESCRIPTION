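Package: skintone
Title: Unsupervised Skin Tone Classification and Segmentation on the Fitzpatrick Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies and segments skin photographs on the six-class
    Fitzpatrick Skin Type (FST) scale by clustering pixels in CIELAB colour
    space and matching cluster centres to an FST reference palette with the
    CIE76 colour difference. Provides twelve clustering model families behind
    one interface, internal clustering validity indices (silhouette,
    Calinski-Harabasz, Davies-Bouldin) with a benchmark harness, an
    Individual Typology Angle (ITA) ground-truth labeller, exact and
    tolerance-based evaluation metrics, a seeded synthetic skin-image
    generator with known FST structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    e1071,
    farver,
    generics,
    ggplot2,
    jpeg,
    jsonlite,
    kernlab,
    mclust,
    optparse,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
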