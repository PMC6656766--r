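test_that("empty-molecule conventions give zero on every property", {
  expect_equal(penalized_logp(""), 0)
  expect_equal(qed(""), 0)
  expect_equal(similarity("", "CCO"), 0)
})

test_that("penalized logP and QED agree with the direct descriptor oracle", {
  # fixtures plus molecules generated by the package itself
  set.seed(4)
  cfg <- qed_config(max_steps = 8L)
  extra <- character(0)
  s <- mol_state("", 0L)
  while (!is_terminal(s, cfg)) {
    acts <- valid_actions(s, cfg)
    s <- mdp_step(s, acts$smiles[sample.int(nrow(acts), 1L)], cfg)
    extra <- c(extra, s$molecule)
  }
  mols <- unique(c(fixture_molecules(), extra))
  expect_gte(length(mols), 30L)
  oracle <- oracle_props(mols)
  expect_equal(penalized_logp(mols), oracle$plogp, tolerance = 1e-8)
  expect_equal(qed(mols), oracle$qed, tolerance = 1e-8)
  expect_equal(mol_props(mols, "logp")$logp, oracle$logp, tolerance = 1e-8)
  expect_equal(mol_props(mols, "sa")$sa, oracle$sa, tolerance = 1e-8)
})

test_that("cycle penalty modes differ only on long rings", {
  # cyclodecane: largest ring 10 -> penalty 4 vs count 1
  expect_equal(penalized_logp("C1CCCCCCCCC1") -
                 penalized_logp("C1CCCCCCCCC1", cycle_mode = "count"),
               -(10 - 6) + 1)
  # cyclohexane: no penalty either way
  expect_equal(penalized_logp("C1CCCCC1"),
               penalized_logp("C1CCCCC1", cycle_mode = "count"))
})

test_that("Tanimoto similarity matches RDKit's own similarity and is symmetric", {
  mols <- fixture_molecules()
  ref <- "CCO"
  oracle <- oracle_props(mols, ref = ref)
  expect_equal(similarity(mols, ref), oracle$tanimoto, tolerance = 1e-12)
  expect_equal(similarity("C", "C"), 1)
  for (m in sample(mols, 8)) {
    expect_equal(similarity(m, ref), similarity(ref, m))
  }
})

test_that("scalarization is the dot product and exactly linear", {
  expect_equal(scalarize(c(0.8, 0.6), c(0.5, 0.5)), 0.7)
  expect_equal(scalarize(c(0.3, 0.9), c(1, 0)), 0.3)
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    r1 <- rnorm(k); r2 <- rnorm(k); w <- rnorm(k)
    a <- rnorm(1); b <- rnorm(1)
    expect_equal(scalarize(a * r1 + b * r2, w),
                 a * scalarize(r1, w) + b * scalarize(r2, w))
  }
  expect_error(scalarize(c(1, 2), c(1, 2, 3)), "length")
})

test_that("multi-objective reward reproduces w*SIM + (1-w)*QED", {
  m0 <- "Cc1ccccc1O"
  for (w in c(0, 0.2, 0.6, 1)) {
    spec <- reward_spec("multi_objective",
                        properties = c("similarity", "qed"),
                        weights = c(w, 1 - w), reference = m0,
                        max_steps = 40L)
    m <- "CCc1ccccc1O"
    expect_equal(reward_value(m, spec),
                 w * similarity(m, m0) + (1 - w) * qed(m))
  }
})

test_that("constrained reward is piecewise with a continuous boundary", {
  m0 <- "C1CCCCC1"
  m <- "CC1CCCCC1"
  sim <- similarity(m, m0)
  base <- penalized_logp(m)
  spec_at <- function(delta) reward_spec("constrained", lambda = 100,
                                         delta = delta, reference = m0,
                                         max_steps = 20L)
  # boundary sits on the unpenalized branch
  expect_equal(constrained_reward(m, spec_at(sim)), base)
  # below the boundary the printed penalty applies
  expect_equal(constrained_reward(m, spec_at(min(1, sim + 0.1))),
               base - 100 * 0.1, tolerance = 1e-9)
  # continuity: penalty vanishes as delta -> sim from above
  expect_equal(constrained_reward(m, spec_at(sim + 1e-9)), base,
               tolerance = 1e-6)
  # the reference molecule itself is never penalized
  expect_equal(constrained_reward(m0, spec_at(1)), penalized_logp(m0))
  # penalty positivity: an unsatisfied constraint always scores lower
  expect_lt(constrained_reward(m, spec_at(min(1, sim + 0.05))), base)
})

test_that("step discounting weights the horizon most heavily", {
  expect_equal(discounted_step_reward(1, 40, 0.9, 40), 1)
  expect_equal(discounted_step_reward(1, 38, 0.9, 40), 0.81)
  expect_equal(discounted_step_reward(2.5, 7, 1, 40), 2.5)
  expect_error(discounted_step_reward(1, 41, 0.9, 40), "horizon")
  # gamma = 1 reduces the return to the undiscounted sum
  raws <- runif(10)
  expect_equal(sum(discounted_step_reward(raws, 1:10, 1, 10)), sum(raws))
})

test_that("relative improvement hits its closed-form anchor points", {
  m0 <- "C1CCCCC1"
  q0 <- qed(m0)
  # same molecule: no improvement
  expect_equal(relative_improvement(m0, m0), 0)
  # generic molecule: matches the formula computed from raw QED values
  m <- "CC(N)=O"
  expect_equal(relative_improvement(m, m0), (qed(m) - q0) / (1 - q0))
  # formula identities at the extremes (checked on the formula itself)
  expect_equal((1 - q0) / (1 - q0), 1)      # QED(m) = 1 maps to 1
})

test_that("range-target reward is zero inside and metric outside", {
  m <- "CCCCCCCC"   # logP 3.3668
  lp <- mol_props(m, "logp")$logp
  spec_in <- reward_spec("range_target", properties = "logp",
                         range = c(lp - 1, lp + 1), max_steps = 40L)
  expect_equal(range_target_reward(m, spec_in), 0)
  spec_above <- reward_spec("range_target", properties = "logp",
                            range = c(lp - 3, lp - 1), max_steps = 40L)
  expect_equal(range_target_reward(m, spec_above), -1)
  # moving the interval closer never lowers the reward
  d <- seq(0, 3, by = 0.5)
  vals <- vapply(d, function(x)
    range_target_reward(m, reward_spec("range_target", properties = "logp",
                                       range = c(lp + x, lp + x + 1),
                                       max_steps = 40L)), numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
  expect_error(reward_spec("range_target", properties = "logp",
                           range = c(2, 1), max_steps = 40L), "inverted")
})

test_that("reward specs validate their contracts", {
  expect_error(reward_spec("multi_objective", properties = c("qed", "similarity"),
                           reference = "C"), "weights")
  expect_error(reward_spec("constrained", reference = NULL), "reference")
  expect_error(reward_spec("constrained", reference = "C", delta = 1.2), "delta")
  expect_error(reward_spec(gamma = 0), "gamma")
})
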