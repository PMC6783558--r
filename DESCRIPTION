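Package: ripresil
Title: Resistance and Resilience Analysis of Disturbed Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the response of microbial communities to disturbance
    in a reference / disturbed / recovery group design: resistance (RS) and
    resilience (RL) indices for abundance, alpha diversity and individual taxa;
    rarefaction, Shannon, Chao1 and Pielou evenness; Bray-Curtis distances with
    ANOSIM, Kruskal-Wallis and Mann-Whitney group comparisons; and genus-level
    co-occurrence networks from thresholded Spearman correlations with topology
    summaries (average degree, path length, clustering, Louvain modularity).
    Includes a synthetic-data generator that emulates a two-area, three-group
    riparian soil study with known ground-truth indices and planted
    correlations, so the whole pipeline is testable without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0),
    vegan,
    xml2
Config/testthat/edition: 3
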