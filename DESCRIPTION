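Package: afclust
Title: Alignment-Free Centroid Clustering of Sequencing Reads by Word Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters short nucleotide reads without alignment, representing each
    read by its n-mer (word) count vector. Implements hard and soft expectation
    maximization under the multinomial model, where the Kullback-Leibler
    divergence is the exact (length-scaled) negative log-likelihood, as well as
    whitened k-means and centroid iteration under L2, d2, d2*, chi-squared and
    symmetrized-KL dissimilarities. Includes bootstrap consensus clustering with
    an average-linkage tree, recall-rate and threshold-sweep ROC/AUC evaluation
    against known read origins, and a seeded simulator for zero-order-composition
    source sequences and substitution-error reads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
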