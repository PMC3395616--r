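Package: rebootnet
Title: Compositionality-Aware Microbial Co-Occurrence Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers signed microbial co-occurrence and co-exclusion networks
    from taxon-by-sample relative abundance tables. Combines an ensemble of
    association measures (Pearson, Spearman, Bray-Curtis, Kullback-Leibler)
    with a compendium of component-wise boosted linear models, assigns
    significance with a permutation-renormalization bootstrap (ReBoot) that
    discounts spurious correlation induced by compositionality, and merges
    the resulting evidence networks by Simes combination with
    Benjamini-Hochberg-Yekutieli false discovery rate control. Includes
    downstream network statistics (degree distributions, Markov clustering,
    modularity, randomization enrichment), phylogenetic and gene-family
    distance annotation of edges, and a synthetic compositional count
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    biomformat,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
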