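Package: hierseg
Title: Agreement Metrics for Hierarchical Music Structure Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing structural annotations of music recordings,
    both flat and hierarchical. Implements the rank-based L-precision,
    L-recall and L-measure computed from meet matrices of labeled
    hierarchies, alongside the classical frame-pairwise classification and
    normalized conditional entropy scores. Also provides an acoustic
    correlation pipeline (tempo, rhythm, chroma and timbre descriptors,
    Gaussian-kernel self-similarity matrices, and a whitened
    annotation-distance), corpus-scale evaluation utilities
    (all-pairs annotator scoring, quadrant/median analysis, two-sample
    Kolmogorov-Smirnov comparison, bootstrap confidence intervals), and
    seeded generators of synthetic hierarchies and structure-correlated
    feature matrices for testing without any corpus download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
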