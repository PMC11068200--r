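Package: psdfrag
Title: Fragmentation Efficiency Analysis for Intact Proteins under
    MALDI-TOF-TOF Post-Source Decay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the aspartic-acid-effect fragmentation of
    intact protein ions under MALDI-TOF-TOF post-source decay (PSD). Predicts
    singly protonated average-mass b- and y-type fragment ions at D/E/N
    backbone cleavage sites, matches them to centroided MS/MS peak lists and
    computes per-site signal scores, extracts per-residue structural
    descriptors (hydrogen bonds, salt bridges, secondary structure, relative
    solvent accessibility) and residue-interaction-network centralities from
    predicted structures, and models signal scores with negative-binomial
    regression plus nonparametric group tests and empirical-CDF comparisons.
    Includes a synthetic-data generator that emulates sequences, structures
    and centroided spectra with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    igraph,
    bio3d,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
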