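Package: dsclust
Title: Double-Target Self-Supervised Clustering of Short Texts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters short, sparse documents (for example medical
    question-and-answer posts) by fusing TF-IDF weights with subword
    skip-gram word embeddings, encoding each document with a bidirectional
    GRU and structured self-attention, and training the encoder end-to-end
    against a double self-supervised target: the Kullback-Leibler divergence
    to a frozen LDA document-topic distribution plus a within-batch k-means
    centroid attraction loss with a linearly climbing weight. Ships a
    labelled synthetic short-text corpus generator, a TF-IDF + k-means
    baseline, and permutation-invariant clustering metrics (optimal-mapping
    accuracy, NMI, ARI, pairwise and macro F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
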