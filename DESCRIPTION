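Package: rankDEG
Title: Multi-Dataset Gene Prioritization by Pairwise Competition and
    Rating Algorithms
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates differential-expression result tables from multiple
    transcriptomics datasets by letting genes compete pairwise on log-fold
    change within each dataset. Pairwise outcomes are aggregated under an
    intersection or union strategy into win/loss/games matrices, genes are
    scored with eight rating algorithms from the sports-ranking literature
    (win-loss ratio, Massey and Colley least squares, Keener's Perron
    eigenvector, Elo, Markov chain, PageRank, and bi-directional PageRank),
    and rankings are validated by leave-one-out cross-validation against
    held-out differentially-expressed-gene calls using ROC AUC and
    prevalence-normalized AUPR. Includes a deterministic synthetic-data
    generator with planted differential genes and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
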