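Package: npnet
Title: Natural Product and Cancer Drug Target Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evidence-graded integration and network analysis of compound-target
    interactions for natural products and approved cancer drugs. Implements a
    three-tier evidence framework with binding-affinity filtering, pathway /
    target / cancer-driver / tumor-type coverage comparison between compound
    classes, hypergeometric driver-gene over-representation with
    Benjamini-Yekutieli false discovery rate control, protein-protein
    interaction network topology comparison with random-control baselines,
    shared-gene pathway crosstalk networks, and weighted compound-compound
    community detection by multilevel modularity optimization. A seeded
    synthetic scenario generator emulates the statistical structure of the
    public source databases so every stage runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
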