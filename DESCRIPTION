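Package: moldqn
Title: Molecule Optimization by Deep Q-Learning on Graph Edits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A valence-constrained molecule-editing Markov decision process
    solved with a bootstrapped double deep-Q-learning agent. States are
    (molecule, step) pairs; actions are atom additions, bond additions and
    bond removals that always yield sanitizable molecules, so every generated
    structure is chemically valid. Rewards include penalized logP, QED,
    Tanimoto-similarity-constrained and scalarized multi-objective designs.
    Ships random, greedy and epsilon-greedy baselines, a two-phase QED
    optimization procedure, evaluation/diversity rollout modes and per-action
    Q-value maps for interpreting learned policies. Chemistry primitives
    (sanitization, canonical SMILES, descriptors, Morgan fingerprints) are
    supplied by RDKit through a persistent helper process.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    processx,
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Python (>= 3.8) with rdkit importable as 'python' on PATH
Config/testthat/edition: 3
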