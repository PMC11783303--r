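Package: immusel
Title: Positive Selection and Selective Constraint on Immune Gene Categories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for comparative analyses of positive
    selection on functional categories of protein-coding genes. Implements
    gene-wide codon-model likelihood-ratio tests for episodic positive
    selection in three variants (with and without site-to-site synonymous
    rate variation and multinucleotide substitutions), model-averaged
    p-values with Benjamini-Hochberg correction, degeneracy-based pN/pS
    estimation with a variant-filter cascade and coverage masking,
    TMM-FPKM expression normalization with the tissue-specificity index
    tau, and a category-level statistical layer (binomial and linear
    models with type-3 tests, Dunnett contrasts against a control
    category, Kruskal-Wallis with Dunn post hoc tests, and partial
    Spearman correlations). A synthetic-data generator emulates every
    input so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    edgeR,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
NeedsCompilation: yes
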