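Package: lpiboost
Title: Imbalance-Aware Boosting of Extra Trees and Decision Trees for
    lncRNA-Protein Interaction Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts lncRNA-protein interactions (LPIs) from sequence
    alone.  lncRNAs and proteins are described by classical sequence
    descriptors (k-mer and gapped k-mer nucleotide composition, zCurve,
    GC content and skews; amino acid and dipeptide composition, CTD,
    conjoint triad, quasi-sequence order, pseudo amino acid composition,
    Moreau-Broto autocorrelation), reduced by PCA and concatenated into
    pair vectors.  Pairs are classified by a boosting ensemble that
    alternates two weak-learner families - small voting forests of
    extremely randomized trees scored by normalized Shannon information
    gain, and exhaustive-search information-gain decision trees - with
    AdaBoost-style sample reweighting to cope with the severe class
    imbalance of interaction data.  Includes three cold-start
    cross-validation schemes (new lncRNAs, new proteins, new pairs), a
    seeded synthetic-data generator with a planted motif signal, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
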