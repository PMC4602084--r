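Package: codonCMA
Title: Codon-Aware Correlated Mutation Analysis for Protein Contact
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coevolution scoring of amino-acid and codon multiple sequence
    alignments for residue-residue contact prediction. Implements the
    classical correlated-mutation statistics (OMES, mutual information,
    MIp with average product correction), mean-field direct coupling
    analysis (DCA/DI), and a sparse inverse-covariance (PSICOV-style)
    scorer, all alphabet-generic so they run on both amino-acid and codon
    alignments. The two levels are combined into the score
    S^alpha(AA)/S(C), which demotes column pairs whose correlation is
    also strong at the codon level; alpha is fitted by maximising the
    median AUC improvement across families with random-split
    cross-validation. Includes contact-map construction from structures
    under C-beta, all-atom and physical-contact definitions, accuracy
    curve and AUC-improvement evaluation, nonparametric significance
    tests (exact Wilcoxon signed-rank and sign tests), and a seeded
    generator of paired codon/amino-acid alignments with planted
    couplings and matching synthetic structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    Biostrings,
    bio3d,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
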