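Package: rnasurf
Title: Structure-Based Prediction of RNA-Binding Preferences on Protein Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts, at each point of a lattice grid around a protein
    surface, the binding preference for seven classes of RNA interaction
    (non-site, phosphate, ribose, adenine, guanine, cytosine, uracil) from a
    radial-shell encoding of the local physicochemical environment, and
    assimilates the per-point predictions into sequence logos and a
    hidden-Markov-model score for RNA letter sequences. Includes PDB
    structure handling, nucleotide decomposition into constituent centroids,
    an alpha-sphere surface filter, homology-aware curation and
    cross-validation, a hierarchical two-level classifier with a residual
    network backbone and a multinomial baseline, trinucleotide-conformer
    clique alignment, and evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
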