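Package: metalbindr
Title: Prediction of Metal-Binding Cysteine and Histidine Residues in
    Electron Transport Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies metal-coordinating cysteine and histidine residues
    in electron transport proteins from sequence context. Candidate
    residues are encoded as 13-residue windows under one of four schemes
    (amino-acid identity, BLOSUM62, PAM250, or logistic-scaled PSI-BLAST
    PSSM profiles), optionally extended with binary indicators for
    significant amino acid pairs (SAAPs) found by a hypergeometric
    enrichment test, and classified with a Gaussian radial basis function
    network that uses every training vector as a center. Includes the full
    evaluation protocol (stratified 10-fold cross-validation, greedy
    forward selection of ranked SAAPs, independent-test evaluation,
    sensitivity/specificity/precision/accuracy/MCC), a PSI-BLAST ASCII
    PSSM parser, and a seeded synthetic-data generator that emulates the
    statistical structure of annotated metal-binding datasets so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
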