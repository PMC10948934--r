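Package: vapTriage
Title: FFAT Motif Scanning and VAP Interactome Triage
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to identify candidate VAP (VAMP-associated protein)
    interactors and triage them through a genetic modifier screen. Implements
    penalty-based position weight matrix scanning of protein sequences for
    conventional FFAT ("two phenylalanines in an acidic tract") and
    Phospho-FFAT motifs over 19-residue windows (six upstream, seven core,
    six downstream; an ideal sequence scores zero), WT-over-binding-dead
    mutant enrichment ranking of immunoprecipitation mass-spectrometry
    spectral counts, ortholog joining and tabulation of an RNAi suppressor
    screen with trigger versus effector classification, and seeded synthetic
    data generators with machine-readable truth records so every stage is
    verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Proteomics, SequenceMatching, MotifDiscovery, MassSpectrometry
Config/testthat/edition: 3
RoxygenNote: 7.3.3
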