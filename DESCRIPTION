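Package: nahdesign
Title: Reaction-Driven Design and SAR Analytics for N-Acylhydrazone Kinase
    Inhibitor Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the computational design of N-acylhydrazone (NAH)
    kinase-inhibitor libraries. Curates carboxylic-acid and aldehyde building
    blocks, enumerates virtual NAH products through the two-step virtual
    synthesis (acid to hydrazide, hydrazide plus aldehyde to E-configured
    acylhydrazone), computes descriptors (Fsp3, stereocenter count, molecular
    formula, monoisotopic and ion-adduct m/z), folds 1024-bit circular
    fingerprints into a two-dimensional principal-component chemical-space
    embedding, checks docked poses against hydrogen-bond pharmacophore
    constraint spheres, and provides quantitative pharmacology analytics:
    fold-potency and fold-selectivity ratios, Cheng-Prusoff Ki conversion,
    kinase-panel summaries, and PAMPA gastrointestinal and blood-brain-barrier
    permeability classification. A seeded synthetic reagent-collection
    generator with planted ground truth supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
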