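Package: furculashape
Title: Eigenshape Morphometrics and Phylogenetic Flight-Mode Inference for
    the Avian Furcula
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Outline morphometrics of the avian furcula (wishbone) coupled
    with phylogenetic comparative methods. Digitized two-dimensional outline
    curves are resampled to equally spaced pseudolandmarks, converted to
    tangent-angle (phi) functions and decomposed by eigenshape analysis
    (standard, extended and multi-view). Eigenshape scores are analysed in a
    phylogenetic framework: Blomberg's K, Abouheif's C, Pagel's lambda and
    phylogenetic eigenvector regression quantify phylogenetic signal;
    simulation-null phylogenetic ANOVA/MANOVA and a phylogenetic Tukey HSD
    test for differences between flight modes; and phylogenetic flexible
    discriminant analysis (pFDA) predicts flight mode for taxa of unknown
    locomotor class, including fossil tips on a time-scaled composite
    phylogeny. A class-conditional synthetic outline generator with
    Brownian-motion phylogenetic covariance supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante,
    MASS,
    jsonlite
Config/testthat/edition: 3
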