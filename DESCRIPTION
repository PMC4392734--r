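Package: linkernet
Title: Discovery and Statistical Assessment of Molecular Interaction
    Networks in Candidate Gene Lists
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Searches a curated molecular-interaction database for networks
    among a user-supplied candidate gene list (for example, differentially
    expressed genes), allowing one non-list "linker" gene per indirect
    connection. Interactions that are only computationally predicted are
    excluded. Discovered networks are scored by the mean number of
    publications supporting their edges, the score is tested against a
    permutation null of resampled edge sets, and enrichment of list genes
    in each network's induced 1-neighbourhood is tested with an upper-tail
    hypergeometric test. Includes a synthetic-data generator with planted
    ground-truth networks, TSV/DOT/JSON reporting, and a command-line
    driver script.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression, Network
RoxygenNote: 7.3.3
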