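Package: prophagr
Title: Prophage Species Delimitation, Host Range and Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Delimits (pro)phage species from nucleotide sequences by
    fragment-based average nucleotide identity (ANIb-style) and paraclique
    graph clustering at the >=95% identity / >=90% coverage species
    thresholds, then integrates the bacterial host population structure:
    per-species host range over MLST sequence types, geographic dispersion
    with Tukey outlier fences, polylysogeny (intra-genome prophage ANI and
    Kruskal-Wallis group tests), exact incidence-based species accumulation
    curves, and comparison of clusterings at alternative thresholds.
    Includes a synthetic prophage-community generator with known species
    structure so the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    Biostrings,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
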