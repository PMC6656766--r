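test_that("cyclohexane atom additions collapse to the four distinct products", {
  cfg <- mdp_config(element_set = c("C", "O"))
  acts <- enumerate_atom_additions("C1CCCCC1", cfg)
  expect_equal(nrow(acts), 4L)
  expect_setequal(acts$smiles,
                  c("CC1CCCCC1", "OC1CCCCC1", "C=C1CCCCC1", "O=C1CCCCC1"))
})

test_that("the empty molecule seeds single atoms and offers no no-op", {
  cfg <- mdp_config(element_set = c("C", "O"))
  acts <- valid_actions(mol_state("", 0L), cfg)
  expect_setequal(acts$smiles, c("C", "O"))
  expect_true(all(acts$kind == "atom_addition"))
})

test_that("bond addition obeys the ring heuristics", {
  cfg <- mdp_config(element_set = c("C", "O"), allowed_ring_sizes = 3:6)
  # every cyclohexane carbon is in the ring: all pairs forbidden
  expect_equal(nrow(enumerate_bond_additions("C1CCCCC1", cfg)), 0L)
  # n-butane: order increases plus ring closures of allowed size
  acts <- enumerate_bond_additions("CCCC", cfg)
  expect_true("C1CCC1" %in% acts$smiles)      # 4-ring allowed here
  expect_true("C=CCC" %in% acts$smiles)       # single -> double
  expect_true("C#CCC" %in% acts$smiles)       # single -> triple
  # with only 5/6-rings allowed the cyclobutane closure disappears
  cfg56 <- mdp_config(element_set = c("C", "O"), allowed_ring_sizes = 5:6)
  expect_false("C1CCC1" %in% enumerate_bond_additions("CCCC", cfg56)$smiles)
  # ethene's double bond can still be increased to a triple bond
  expect_true("C#C" %in% enumerate_bond_additions("C=C", cfg)$smiles)
  # aromatic bonds are never modified
  expect_equal(nrow(enumerate_bond_additions("c1ccccc1", cfg)), 0L)
})

test_that("bond removal applies the disconnection cleanup rule", {
  # ethane would leave two lone atoms: no removal action at all
  expect_equal(nrow(enumerate_bond_removals("CC")), 0L)
  # propane leaves one lone atom, which is deleted: product is ethane
  expect_equal(enumerate_bond_removals("CCC")$smiles, "CC")
  # 2-butyne's triple bond: decrease to double, single, or cleave
  acts <- enumerate_bond_removals("CC#CC")
  expect_setequal(acts$smiles, c("CC=CC", "CCCC", "C#CC"))
  # opening a ring keeps one component
  expect_equal(enumerate_bond_removals("C1CCCCC1")$smiles, "CCCCCC")
})

test_that("no emitted product is fragmented and all sanitize", {
  cfg <- qed_config()
  for (m in fixture_molecules()) {
    acts <- valid_actions(mol_state(m, 0L), cfg)
    expect_false(any(grepl(".", acts$smiles, fixed = TRUE)), info = m)
    expect_equal(validity_fraction(acts$smiles), 1, info = m)
  }
})

test_that("enumeration equals the brute-force edit-and-sanitize oracle", {
  cfg <- mdp_config(element_set = c("C", "O", "N"),
                    allowed_ring_sizes = c(5L, 6L, 7L))
  mols <- fixture_molecules()
  oracle <- oracle_actions(mols, elements = cfg$element_set,
                           ring_sizes = cfg$allowed_ring_sizes)
  for (k in seq_along(mols)) {
    m <- mols[k]
    expect_setequal(enumerate_atom_additions(m, cfg)$smiles, oracle[[k]]$atom)
    expect_setequal(enumerate_bond_additions(m, cfg)$smiles, oracle[[k]]$bond)
    expect_setequal(enumerate_bond_removals(m)$smiles, oracle[[k]]$removal)
  }
})

test_that("rings closed by bond addition always have allowed sizes", {
  cfg <- mdp_config(element_set = "C", allowed_ring_sizes = c(5L, 6L))
  # an octane chain could close rings of size 3..8; only 5/6 may appear
  acts <- enumerate_bond_additions("CCCCCCCC", cfg)
  new_rings <- vapply(acts$smiles, function(s)
    mol_props(s, "maxring")$maxring, numeric(1))
  expect_true(all(new_rings %in% c(0, 5, 6)))
  expect_true("C1CCCCC1CC" %in% acts$smiles ||
                "CCC1CCCCC1" %in% acts$smiles)
})

test_that("transitions are deterministic, pure, and guarded", {
  cfg <- mdp_config(element_set = c("C", "O"), max_steps = 5L)
  s <- mol_state("C1CCCCC1", 3L)
  nxt <- mdp_step(s, "OC1CCCCC1", cfg)
  expect_equal(nxt$molecule, "OC1CCCCC1")
  expect_equal(nxt$steps_taken, 4L)
  # no-modification keeps the molecule and advances the clock
  noop <- mdp_step(s, "C1CCCCC1", cfg)
  expect_equal(noop$molecule, s$molecule)
  expect_equal(noop$steps_taken, 4L)
  # stepping twice gives identical results (pure function)
  expect_identical(mdp_step(s, "OC1CCCCC1", cfg), nxt)
  # contract errors
  expect_error(mdp_step(s, "CCCCCCCCCC", cfg), "not valid")
  term <- mol_state("C", 5L)
  expect_error(mdp_step(term, "CC", cfg), "terminal")
  expect_error(valid_actions(term, cfg), "terminal")
})

test_that("molecules stay valid and connected along random walks", {
  cfg <- mdp_config(element_set = c("C", "O", "N"), max_steps = 15L,
                    allowed_ring_sizes = c(5L, 6L))
  set.seed(99)
  for (ep in 1:4) {
    s <- mol_state("", 0L)
    while (!is_terminal(s, cfg)) {
      acts <- valid_actions(s, cfg)
      expect_gt(nrow(acts), 0L)
      pick <- acts$smiles[sample.int(nrow(acts), 1L)]
      expect_no_error(parse_molecule(pick))
      expect_false(grepl(".", pick, fixed = TRUE))
      s <- mdp_step(s, pick, cfg)
    }
  }
})

test_that("stereochemistry is dropped from inputs with a warning", {
  expect_warning(p <- parse_molecule("C[C@H](N)C(=O)O"), "stereo")
  expect_false(grepl("@", p$smiles))
})

test_that("action sets export as JSON lines", {
  cfg <- mdp_config(element_set = "C")
  acts <- valid_actions(mol_state("CC", 0L), cfg)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_actions_jsonl(acts, path)
  lines <- readLines(path)
  expect_length(lines, nrow(acts))
  rec <- jsonlite::fromJSON(lines[1])
  expect_named(rec, c("kind", "result_smiles"))
})

test_that("configuration invariants are enforced", {
  expect_error(mdp_config(element_set = character(0)), "element_set")
  expect_error(mdp_config(allowed_ring_sizes = c(2, 5)), "ring")
  expect_error(mdp_config(max_steps = 0), "max_steps")
})
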