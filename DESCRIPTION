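Package: dynetsim
Title: Similarity Indices and Simulation for Dynamic Weighted Networks
Version: 0.1.0
Authors@R: person("dynetsim", "maintainers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Quantifies the similarity of dynamic (time-evolving) weighted
    networks such as longitudinal brain connectomes. Implements the Dynamic
    Network Similarity (DNS) index, computed on the concatenated long-vector
    representation of a network sequence, and the Dynamic Network Evolution
    Similarity (DNES) index, computed on per-edge time series, together with
    four traditional snapshot comparators (Dice, Jaccard,
    normalized-Laplacian spectral similarity, normalized Pearson). Includes
    a controlled-variable simulator of evolving network pairs, the six
    validation experiments built on it, a group-comparison pipeline from ROI
    time series to nonparametric same-therapy versus different-therapy
    statistics, a synthetic cohort generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
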