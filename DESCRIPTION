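Package: ppikit
Title: Protein Interactome Characterization from AP-MS and BRET Assays
Version: 0.1.0
Authors@R:
    person("Elias", "Kern", email = "elias.kern@posteo.net", role = c("aut", "cre"))
Description: Tools for characterizing a transcription factor's protein
    interactome from affinity purification-mass spectrometry (AP-MS) data
    and live-cell validation assays. Implements Mascot-score peptide
    filtering and emPAI abundance estimation, a contaminant/control/
    CRAPome/replicate filtering funnel, confidence-scored interaction
    network construction with MCODE dense-cluster detection, gene-set
    annotation and candidate prioritization for neurodevelopmental
    disorder genes, corrected-ratio analysis of bioluminescence resonance
    energy transfer (BRET) plate readings with one-way ANOVA and Tukey
    post-hoc tests, and inference of protein binding regions from panels
    of truncating and missense variants. A synthetic-data generator
    emulates every input with known ground truth so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
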