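Package: sahhtools
Title: Substrate-Preference Annotation for SAH/SIH Hydrolases from
    Sequence, Structure and Assay Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for the S-adenosyl-L-homocysteine hydrolase
    (SAHH/SIHH) enzyme family. Extracts the five-residue nucleobase-binding
    fingerprint motif from protein sequences and predicts substrate
    preference (SAH vs SIH), detects architecture features (a 40-residue
    catalytic-domain segment, C-terminal length), scans proteomes for
    DadD/MTAN homologues and infers SAH-degradation pathway routes.
    Measures active-site geometry from crystal-structure coordinates:
    molecular-gate state (His-IN/His-OUT) with rotamer analysis,
    hydrogen-bond enumeration, nucleobase tautomer inference, monovalent
    cation detection, Kabsch superposition and asymmetric-unit chain RMSD,
    interdomain open/closed rotation angles and peptide-plane flips.
    Converts HPLC peak-area tables into semi-quantitative conversion
    categories and substrate-preference calls, and reports concordance
    between motif-based predictions and assay results. Ships a synthetic
    fixture generator (toy active sites, motif-planted sequences, noisy
    peak tables) so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
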