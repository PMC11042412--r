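Package: diaseq
Title: De Novo Peptide Sequencing for Data-Independent Acquisition Mass
    Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequencing peptides de novo from multiplexed data-independent
    acquisition (DIA) tandem mass spectra, in which every MS2 scan mixes
    fragments from several co-isolated precursors.  Assembles per-precursor
    model inputs (elution profile, binned MS2 spectra, nearest MS1 scan),
    builds product-ion intensity arrays over eight b/y-family ion types,
    and decodes residue sequences with a transformer encoder-decoder whose
    spectrum encoder fuses the input streams by concatenation, standard
    attention, or multi-head attention.  Includes beam-search inference
    under a precursor-mass constraint, mass-tolerance evaluation metrics
    (amino-acid and peptide precision/recall, precision-coverage curves,
    AUC), and a synthetic multiplexed-DIA simulator with known ground
    truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
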