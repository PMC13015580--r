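Package: adaredit
Title: Structure-Explicit Graph Attention Prediction of A-to-I RNA Editing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts adenosine-to-inosine (A-to-I) RNA editability of
    individual adenosines inside double-stranded RNA duplexes. Each candidate
    adenosine is encoded as a position-centric nucleotide graph built from the
    duplex sequence and its dot-bracket secondary structure (backbone and
    base-pair edges), and scored by a multi-head graph attention network;
    a bio-aware variant adds typed edges, thermodynamic and stem-loop node
    features, and a k-mer convolutional sequence branch. The package includes
    dataset construction from per-adenosine editing tables (classification,
    class balancing, 80:20 splitting, cross-species cluster/segment/negative
    selection), F1-optimized threshold and checkpoint selection with
    threshold-free AUROC/AUPRC evaluation, attention-based interpretability
    with gradient-boosted validation and Shapley feature ranking, four
    structure-coupled in silico mutagenesis analyses, and a self-consistent
    synthetic duplex generator with planted editing rules for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
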