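Package: stallscope
Title: Proteogenomic Analysis of Translation at an Unassigned Stop Codon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise how ribosomes resolve translation at an
    unassigned (orphan) UAG codon in a genomically recoded organism. Builds
    the theoretical protein and peptide search libraries for every
    translational outcome at the stall (near-cognate suppression, ribosomal
    frameshifting, tmRNA/ssrA tagging, loss of translational fidelity),
    digests them with trypsin rules, infers and classifies the translational
    events behind observed C-terminal peptides (minimal-junction
    explanations, net bases skipped, tag detection), computes monoisotopic
    peptide masses and b/y fragment-ion series for manual spectrum
    validation, simulates translation-outcome pools with known event
    structure, and re-implements the supporting assay statistics (growth
    curve doubling time and maximum OD600, segmented western-blot
    calibration, conjugation percent transfer, relative phage titer).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
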