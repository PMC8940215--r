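Package: degradomics
Title: Caspase Cleavage-Site Consensus Motifs from N-Terminomics Degradomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying caspase cleavage-site consensus motifs
    from neo-N-terminal peptide evidence. Derives aspartate (D|X) cleavage
    events from replicate-structured peptide tables mapped onto a proteome,
    tests single-residue subsite motifs (P4-P2) for enrichment with
    replicate-weighted mid-p hypergeometric tests under two-stage linear
    step-up false discovery rate control, tests motif-annotation association
    (e.g. with the GO term "structural constituent of cytoskeleton") using a
    Monte Carlo protein-cleavage null model, and selects candidate consensus
    motif pairs on a specificity/coverage Pareto frontier. Includes a
    synthetic degradome generator with known ground truth so every stage of
    the analysis can be calibrated and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
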