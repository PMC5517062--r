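Package: vivominer
Title: Text Mining of In Vivo Bioassay Descriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining curator-written descriptions of whole-animal
    (in vivo) drug-screening assays. Normalizes and chunks assay
    descriptions with a shallow part-of-speech grammar, extracts mentions
    of rodent genetic strains, induced and transgenic disease models and
    phenotypes with dictionary- and rule-based named entity recognition,
    learns a word-embedding semantic space of the corpus, classifies
    assays by the ATC class of reference drugs with random forests under
    assay- and document-aware cross-validation, and builds the bipartite
    drug/animal-model network. Includes a synthetic corpus generator that
    emulates ChEMBL-style descriptions with gold annotations so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    Rtsne,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
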