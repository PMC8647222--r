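Package: funcxfer
Title: Cross-Species Protein Molecular Function Prediction from Protein
    Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts Gene Ontology molecular function terms for proteins
    from fixed-length protein-level embeddings, and characterizes how well
    such predictions transfer across species. Provides an ontology DAG with
    true-path propagation, term depth and Resnik information content;
    readers for OBO, GAF/TSV annotation, BLAST tabular, InterPro and
    embedding files; residue-embedding layer combination and mean pooling;
    per-term ridge logistic regression and a multi-label multilayer
    perceptron with GO-hierarchy-consistent posterior correction; a
    homology-hit term-frequency baseline; CAFA-style term-centric and
    protein-centric evaluation with semantic distance and bootstrap
    confidence intervals; performance-characterization statistics
    (depth/support/length correlations, a protein-length probe, InterPro
    similarity summaries, GO-category medians); and a seed-deterministic
    synthetic-world generator for end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
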