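Package: apmsquant
Title: Label-Free Quantification, Enrichment Scoring and Network Assembly
    for Affinity-Purified Protein Complexes
Version: 0.1.0
Authors@R:
    person("APMS", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for affinity-purification mass
    spectrometry (AP-MS) of native protein complexes resolved by blue-native
    PAGE. Computes spectral-index quantification normalized to global
    intensity (SI_GI) from peptide-spectrum-match tables, identifies
    bait-enriched proteins against IgG controls with Welch t-tests and
    replicate-consistency filters, performs z-transformed principal component
    analysis of complex composition, assembles abundance-scaled interaction
    networks from offline evidence tables, and localizes phosphosites with
    the A-score cumulative-binomial algorithm. Ships a synthetic-data
    generator with planted complexes and planted phosphosites for testing
    and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
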