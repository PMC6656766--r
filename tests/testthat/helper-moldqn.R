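# Shared fixtures and independent-oracle helpers.

# Diverse small molecules covering chains, branches, multiple bonds,
# saturated and aromatic rings, heteroatoms and fused systems.
fixture_molecules <- function() {
  c("C", "CC", "CCC", "CCCC", "CC(C)C", "CC(C)(C)C",
    "C=C", "C#C", "CC#CC", "C=CC=C",
    "CCO", "CC=O", "CC(C)=O", "CCN", "CC#N", "CC(N)=O",
    "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCOC1", "C1CCNCC1",
    "c1ccccc1", "c1ccccc1O", "c1ccncc1", "Cc1ccccc1",
    "O=C1CCCCC1", "C1CCC2CCCCC2C1")
}

oracle_python <- function() moldqn:::chem_python()

run_oracle <- function(script, req, simplify = TRUE) {
  out <- system2(oracle_python(),
                 c(shQuote(testthat::test_path(script)),
                   shQuote(as.character(jsonlite::toJSON(req, auto_unbox = TRUE)))),
                 stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = simplify)
}

# Brute-force edit-and-sanitize enumeration, fully inside RDKit. Accepts a
# vector of molecules (one python call) and returns a list per molecule of
# character vectors atom / bond / removal.
oracle_actions <- function(smiles, elements = c("C", "O", "N"),
                           ring_sizes = c(5L, 6L, 7L)) {
  res <- run_oracle("oracle_actions.py",
                    list(smiles = I(smiles), elements = I(elements),
                         ring_sizes = I(ring_sizes)),
                    simplify = FALSE)
  lapply(res, function(r) lapply(r, function(x)
    as.character(unlist(x, use.names = FALSE))))
}

# Direct RDKit descriptor/fingerprint calls (no package code).
oracle_props <- function(smiles, ref = NULL) {
  req <- list(smiles = I(smiles))
  if (!is.null(ref)) req$ref <- ref
  run_oracle("oracle_props.py", req)
}

qed_config <- function(max_steps = 40L)
  mdp_config(element_set = c("C", "O", "N"), max_steps = max_steps,
             allowed_ring_sizes = c(5L, 6L, 7L))

qed_spec <- function(max_steps = 40L)
  reward_spec("single_property", properties = "qed", gamma = 0.9,
              max_steps = max_steps)

plogp_spec <- function(max_steps = 38L)
  reward_spec("single_property", properties = "plogp", gamma = 0.9,
              max_steps = max_steps)

# A tiny agent suitable for fast unit tests.
tiny_agent <- function(..., seed = 1L)
  dqn_agent(hidden = c(16L, 8L), heads = 3L, replay_capacity = 64L,
            batch_size = 8L, warmup = 0L, target_sync = 5L, lr = 1e-3,
            seed = seed, ...)

# Synthetic replay transition with random fingerprint bits.
random_transition <- function(heads, nbits = 2048L, terminal = FALSE,
                              n_succ = 3L, reward = stats::rnorm(1),
                              mask = rep(TRUE, heads)) {
  moldqn:::make_transition(
    act_onbits = sample.int(nbits, 20L),
    act_steps = sample(0:10, 1L),
    reward = reward,
    terminal = terminal,
    succ_onbits = if (terminal) list() else
      replicate(n_succ, sample.int(nbits, 20L), simplify = FALSE),
    succ_steps = sample(0:10, 1L),
    mask = mask)
}
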