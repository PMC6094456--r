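Package: teanet
Title: Metabolite-Correlated Gene Co-Expression Network Analysis for Tea Plant Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for relating tissue metabolite contents
    (catechins, theanine, caffeine) to gene co-expression modules in bulk RNA-seq
    of tea plant tissues. Computes FPKM from fragment counts, applies
    low-expression filters, calls differentially expressed genes between pooled
    tissue libraries with the Audic-Claverie exact count test, builds a weighted
    (soft-thresholded) co-expression network with topological-overlap
    dissimilarity, detects and merges modules, correlates module eigengenes with
    metabolite traits (Pearson r, Student-t p, Fisher-Z confidence intervals),
    tests modules for pathway over-representation with the hypergeometric upper
    tail and Benjamini-Hochberg adjustment, and ranks intramodular hub genes.
    Includes a synthetic-data generator with planted modules, trait couplings
    and pathway enrichments so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
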