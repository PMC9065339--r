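Package: drugsite
Title: Drug-Binding-Site Prediction for DNA-Binding Proteins from
    Residue Interaction Networks and Sequence Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Labels drug-binding residues in protein-ligand complex
    structures by a 6.5 Angstrom distance criterion, builds residue
    interaction networks and computes seven per-residue topological
    descriptors (betweenness, closeness, eigenvector centrality,
    eccentricity, degree, clustering coefficient, average nearest-neighbour
    degree), parses PSI-BLAST position-specific scoring matrices, and
    assembles 27-dimensional per-residue feature tables for gradient-boosted
    binding-site classification with random under-sampling,
    cross-validation, and independent-set evaluation. Includes feature
    distribution analyses for binding versus non-binding residues,
    amino-acid property-index summaries, and fully synthetic structure,
    profile, and dataset generators for reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    igraph,
    optparse,
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
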