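Package: cionaconn
Title: Quantitative Analysis of an Ascidian Larval Connectome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of a whole-larva synaptic
    connectome reconstructed from a serial-section electron microscopy
    annotation table, modelled on the Ciona intestinalis larval central
    nervous system. Builds weighted directed (chemical synapse) and
    undirected (gap junction) connectivity tables in which edge weight is
    the cumulative depth of synaptic contact in micrometres; computes
    synapse-level descriptive statistics (polyad, unpolarized and
    dense-core-vesicle fractions, per-neuron synapse loads and their
    scaling with partner number), whole-network statistics (clustering,
    characteristic path length, heterogeneity, centralization),
    pairwise reciprocity, left/right asymmetry measures (sided cell
    counts, neuromuscular left:right ratios, relay-input laterality,
    side-sorted matrices, homologous-pair edge differences), and minimal
    sensory-to-motor pathway enumeration. Includes a seeded synthetic
    connectome generator with the marginal statistics of the real data so
    every analysis is testable without the deposited annotation files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
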