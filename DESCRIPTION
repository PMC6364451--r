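Package: knapcharge
Title: Knapsack-Based Assignment of Partial Atomic Charges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated assignment of partial atomic charges to query
    molecules from a database of previously parameterised molecules.
    Chemical environments are modelled as rooted k-neighbourhood
    subgraphs grouped into isomorphism classes, each carrying a
    Friedman-Diaconis-binned histogram of observed charges. Charge
    assignment is cast as an epsilon-multiple-choice knapsack problem
    (one candidate charge per atom, total charge constrained to a
    window around the target) and solved exactly by a pseudo-polynomial
    dynamic program and by branch-and-bound on the binary integer
    programming formulation. Includes naive per-atom baselines
    (mean/median/mode), a leave-one-out evaluation harness, a synthetic
    corpus generator with ground-truth environment charge models, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'mckp.R'
    'neighbourhood.R'
    'histogram.R'
    'envdb.R'
    'assigner.R'
    'synthdata.R'
    'evaluate.R'
    'cli.R'
    'knapcharge-package.R'
    'molgraph.R'
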