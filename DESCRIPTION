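Package: mddpalm
Title: Protein S-Palmitoylation Site Prediction with Motif Decomposition
    and Two-Layered Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies protein S-palmitoylation sites from sequence.
    Extracts cysteine-centered 21-mer windows, encodes them with six
    sequence feature schemes (orthogonal binary, amino acid composition,
    amino acid pair composition, BLOSUM62 substitution scores, position
    weight matrix, position-specific scoring matrix with logistic
    normalization, and accessible surface area), clusters substrate
    motifs by maximal dependence decomposition using a chi-square test of
    positional dependence over five amino-acid property groups, and
    stacks per-motif RBF-kernel support vector machines into a
    two-layered probabilistic classifier. Includes evaluation machinery
    (sensitivity, specificity, accuracy, Matthews correlation
    coefficient, ROC/AUC, stratified k-fold cross-validation), a seeded
    synthetic fragment generator with planted property-group motifs, and
    command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
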