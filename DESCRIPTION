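Package: mtumortree
Title: Weighted Consensus of Tumor Evolutionary Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for summarising conflicting tumor evolutionary histories
    into a single consensus tree. An m-tumor tree is a rooted tree whose
    nodes are labelled by disjoint clusters of somatic mutations that
    together partition the mutation set. Given several such trees for one
    patient, each carrying a confidence weight, the package finds the
    m-tumor tree minimising the total weighted ancestor-descendant (AD)
    distance to the inputs by solving an integer linear program over
    pairwise ancestral-relation variables and transitively reducing the
    resulting relation. Includes exact enumeration of all co-optimal
    consensus trees, ancestor-descendant and parent-child tree distances,
    a majority-rule harmonizer for inputs over different mutation sets, a
    clonal-tree simulator with sum-rule-consistent mutation frequencies, a
    brute-force consensus oracle for small mutation sets, and an
    evaluation harness for weighting-scheme experiments and weight-simplex
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python3 with scipy (>= 1.9) for the MILP backend
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
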