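Package: mechstep
Title: Parsimony-Based Prediction of Multi-Step Enzyme Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts ranked, elementally and charge-balanced multi-step
    enzyme mechanisms from overall reaction stoichiometry alone. Reactions
    are abstracted into moiety-count vectors (every non-hydrogen atom
    classified by its first bonding shell), elementary mechanistic steps
    become signed moiety-change rules, and an exact integer optimization
    with integer-cut enumeration returns the most parsimonious orderings
    of rules that reproduce the net reaction change while keeping every
    intermediate chemically available. Candidates are re-ranked by their
    maximal unordered similarity to a database of curated mechanisms.
    Includes synthetic-instance generators and brute-force oracles for
    validation, a batch annotation pipeline with an outcome taxonomy, and
    compilation of candidate mechanisms into a network of competing
    catalytic strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (used for SMILES parsing)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
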