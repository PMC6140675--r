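Package: lucifind
Title: Homology Screening, Isotope-Label Mass Spectrometry and COI
    Delimitation for Copepod Bioluminescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for characterising the molecular basis of
    copepod bioluminescence from assembled transcriptomes and LC-MS peak
    lists. Predicts open reading frames with a configurable minimum
    length, screens them against local luciferase, photoprotein and
    luciferin-synthesis protein databases by optimal local alignment with
    Karlin-Altschul bitscore statistics, applies a reciprocal
    bitscore-comparison rule against a curated reference database, scans
    complete predicted proteins for the C-terminal Phe-Tyr-Tyr
    coelenterazine-precursor motif, verifies stable-isotope (13C)
    labelling of coelenterazine-pathway compounds by exact-mass extracted
    ion chromatogram analysis, and delimits species from COI barcode
    alignments by uncorrected p-distance thresholding with a
    neighbor-joining tree. Includes seeded synthetic-data generators with
    ground-truth tables so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
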