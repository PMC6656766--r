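# moldqn

Molecule optimization by deep Q-learning on molecular-graph edits, for
cheminformatics and drug-discovery researchers who want a generative
optimizer with *guaranteed* chemical validity and no pre-training dataset.

Molecule design is cast as a finite-horizon Markov decision process: a
state is a pair (molecule, step count) and an action is a single
valence-legal edit — adding an atom of an allowed element, creating or
increasing a bond, or decreasing/removing one — identified with the
molecule it produces. Illegal edits are never enumerated, so every
reachable molecule sanitizes; validity is a property of the action space,
not a sampling statistic. The MDP is solved by a multi-head
("bootstrapped") deep Q-network with double Q-learning and a Huber loss,
scoring candidate successor states through their Morgan fingerprint plus
the remaining-step count, with per-step rewards discounted as
γ^(T−t) so the final molecule weighs most:

    Q(s, a) = f_θ(φ(s')),   y = r + Q_θ⁻(argmax_a Q_θ(s', a)),
    r_t = γ^(T−t) · R(m_t),  R ∈ {penalized logP, QED, w·SIM + (1−w)·QED,
                                  similarity-constrained logP, range target}

Random-walk, reward-greedy and ε-greedy baselines, a two-phase QED design,
similarity-constrained optimization, diversity evaluation modes and
per-action Q-value maps for interpretation are included. Chemistry
primitives (sanitization, canonical SMILES, descriptors, fingerprints) are
supplied by RDKit through a persistent helper process: the package needs a
`python` on the PATH with `rdkit` importable.

## Worked example

```r
library(moldqn)

# The action space of cyclohexane with elements {C, O}: the six ring
# carbons are symmetry-equivalent, so all atom additions collapse to four
# distinct products; ring atoms admit no bond addition, and opening the
# ring yields hexane.
cfg <- mdp_config(element_set = c("C", "O"), max_steps = 40)
valid_actions(mol_state("C1CCCCC1", 0), cfg)
#>              kind     smiles
#> 1   atom_addition  CC1CCCCC1
#> 2   atom_addition  OC1CCCCC1
#> 3   atom_addition C=C1CCCCC1
#> 4   atom_addition O=C1CCCCC1
#> 5    bond_removal     CCCCCC
#> 6 no_modification   C1CCCCC1

penalized_logp(c("", "CCCCCCCC"))   # logP - SA - large-ring penalty
#> [1] 0.000000 2.062037

# Reward-greedy baseline on QED from the empty molecule: greedy seeds
# ammonia (QED 0.398) and no edit improves it, so it holds to the horizon —
# a textbook local optimum that learned policies escape.
cfgq <- mdp_config(element_set = c("C", "O", "N"), max_steps = 40,
                   allowed_ring_sizes = c(5, 6, 7))
specq <- reward_spec("single_property", properties = "qed", max_steps = 40)
run_baseline("greedy", cfgq, specq, n_episodes = 1)$top
#>   smiles     score
#> 1      N 0.3975551

# A short training run (minutes on one CPU; full-scale runs use
# n_episodes = 5000 with the default [1024, 512, 128, 32] network).
res <- train_dqn(cfgq, specq, n_episodes = 300, seed = 11,
                 hidden = c(128, 64, 32), heads = 4, batch_size = 24,
                 train_every = 4, lr = 1e-3)
res$report$top$score[1]
#> [1] 0.7245195   # vs 0.6528583 for a matched 100-episode random walk
```

A thin CLI wrapping these functions is installed at
`inst/cli/moldqn.R` (`train | baseline | evaluate | constrained`), driven
by a YAML run configuration (see `?read_run_config`).

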