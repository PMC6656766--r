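test_that("run reports rank unique molecules and ignore episode order", {
  term <- c("C", "CC", "CC", "CCO", "C")
  sc <- c(0.1, 0.5, 0.5, 0.3, 0.1)
  rep1 <- run_report(term, sc, k = 3L)
  expect_equal(rep1$top$smiles, c("CC", "CCO", "C"))
  expect_equal(rep1$top$score, c(0.5, 0.3, 0.1))
  perm <- c(4, 2, 1, 5, 3)
  rep2 <- run_report(term[perm], sc[perm], k = 3L)
  expect_equal(rep2$top, rep1$top)
  # window: only the last N terminals ("CCO", "C") count
  rep3 <- run_report(term, sc, window = 2L)
  expect_equal(rep3$top$smiles, c("CCO", "C"))
  expect_equal(rep3$n_terminals, 2L)
})

test_that("the greedy baseline is deterministic end to end", {
  cfg <- qed_config(max_steps = 5L)
  spec <- qed_spec(max_steps = 5L)
  a <- run_baseline("greedy", cfg, spec, n_episodes = 1L, seed = 1L)
  b <- run_baseline("greedy", cfg, spec, n_episodes = 1L, seed = 999L)
  expect_identical(a$top, b$top)
  expect_equal(a$validity, 1)
})

test_that("epsilon-greedy interpolates random and greedy", {
  cfg <- qed_config(max_steps = 4L)
  spec <- qed_spec(max_steps = 4L)
  greedy <- run_baseline("greedy", cfg, spec, n_episodes = 1L, seed = 1L)
  eps0 <- run_baseline("eps_greedy", cfg, spec, n_episodes = 1L, seed = 1L,
                       epsilon = 0)
  expect_identical(eps0$top, greedy$top)
  rnd <- run_baseline("random", cfg, spec, n_episodes = 3L, seed = 7L)
  expect_equal(rnd$validity, 1)
  expect_equal(rnd$n_terminals, 3L)
})

test_that("a short DQN run trains, logs and reports", {
  cfg <- mdp_config(element_set = c("C", "O"), max_steps = 6L,
                    allowed_ring_sizes = c(5L, 6L))
  spec <- qed_spec(max_steps = 6L)
  log <- withr::local_tempfile(fileext = ".csv")
  ckpt <- withr::local_tempfile(fileext = ".rds")
  res <- train_dqn(cfg, spec, n_episodes = 6L, seed = 2L,
                   hidden = c(16L, 8L), heads = 2L, batch_size = 8L,
                   replay_capacity = 64L, warmup = 4L, target_sync = 5L,
                   log_csv = log, checkpoint = ckpt)
  expect_s3_class(res$report, "run_report")
  expect_equal(nrow(res$history), 6L)
  expect_equal(res$history$epsilon[1], 1)
  expect_true(all(diff(res$history$epsilon) <= 0))
  expect_true(file.exists(log))
  expect_true(file.exists(ckpt))
  expect_equal(res$report$validity, 1)
  # rewards carry the gamma^(T-t) convention: the terminal factor is 1
  expect_true(all(is.finite(res$report$returns)))
  # horizon mismatch is rejected
  expect_error(train_dqn(cfg, qed_spec(max_steps = 40L), n_episodes = 1L),
               "horizon")
})

test_that("two-phase QED training restarts from the best phase-one molecules", {
  cfg <- mdp_config(element_set = c("C", "O"), max_steps = 4L,
                    allowed_ring_sizes = c(5L, 6L))
  spec <- qed_spec(max_steps = 4L)
  res <- train_two_step_qed(cfg, spec, n_episodes_phase1 = 4L,
                            n_episodes_phase2 = 3L, seed = 3L,
                            hidden = c(16L, 8L), heads = 2L,
                            batch_size = 8L, replay_capacity = 64L,
                            warmup = 100L)
  expect_true(length(res$start_pool) >= 1L)
  expect_true(all(nzchar(res$start_pool)))
  # phase-two episodes begin at pool molecules: their terminals exist
  expect_equal(res$phase2$report$n_terminals, 3L)
  # pool is the top unique phase-one terminals by score
  p1 <- res$phase1$report
  expected <- moldqn:::top_unique(p1$terminals, p1$scores, 5L)
  expect_identical(res$start_pool, expected)
})

test_that("argmax evaluation is deterministic and eps=0 matches it", {
  cfg <- mdp_config(element_set = c("C", "O"), max_steps = 3L,
                    allowed_ring_sizes = c(5L, 6L))
  spec <- qed_spec(max_steps = 3L)
  agent <- dqn_agent(hidden = c(16L, 8L), heads = 2L, seed = 4L)
  e1 <- evaluate_agent(agent, cfg, spec, mode = "argmax", head = 2L)
  e2 <- evaluate_agent(agent, cfg, spec, mode = "argmax", head = 2L)
  expect_identical(e1[[1]]$smiles, e2[[1]]$smiles)
  e3 <- evaluate_agent(agent, cfg, spec, mode = "eps", epsilon = 0, head = 2L)
  expect_identical(e3[[1]]$smiles, e1[[1]]$smiles)
})

test_that("Q-proportional sampling is uniform when all Q-values tie", {
  cfg <- mdp_config(element_set = "C", max_steps = 1L,
                    allow_bond_addition = FALSE, allow_bond_removal = FALSE,
                    start_molecule = "C")
  spec <- qed_spec(max_steps = 1L)
  agent <- dqn_agent(hidden = c(8L), heads = 1L, seed = 5L)
  # zero the network: every candidate scores exactly 0
  agent$net$W <- lapply(agent$net$W, function(w) w * 0)
  acts <- valid_actions(mol_state("C", 0L), cfg)
  # add a carbon by a single/double/triple bond, or leave unchanged
  expect_setequal(acts$smiles, c("CC", "C=C", "C#C", "C"))
  n_acts <- nrow(acts)
  eps <- evaluate_agent(agent, cfg, spec, mode = "softmax_q",
                        n_episodes = 400L, seed = 6L)
  firsts <- vapply(eps, function(e) e$smiles[1], character(1))
  counts <- table(factor(firsts, levels = acts$smiles))
  p <- 1 / n_acts
  expect_true(all(abs(counts - 400 * p) < 3 * sqrt(400 * p * (1 - p))))
})

test_that("constrained experiment reports improvement and constraint satisfaction", {
  starts <- c("CCO", "CCCO")
  cfg <- mdp_config(element_set = c("C", "O"), max_steps = 2L,
                    allowed_ring_sizes = c(5L, 6L))
  res <- constrained_experiment(starts, delta = 0, n_episodes = 2L,
                                config = cfg, seed = 7L,
                                hidden = c(16L, 8L), heads = 2L,
                                batch_size = 8L, warmup = 100L)
  expect_equal(nrow(res$results), 2L)
  # delta = 0: the similarity constraint is vacuous, success everywhere
  expect_true(all(res$results$success))
  expect_equal(res$results$improvement,
               penalized_logp(res$results$final) -
                 penalized_logp(res$results$start))
  # an unchanged molecule scores improvement 0 and satisfies any delta
  expect_equal(similarity("CCO", "CCO"), 1)
  expect_error(constrained_experiment(character(0)), "start molecules")
})

test_that("SMILES files read one molecule per line with optional names", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO ethanol", "C1CCCCC1", "# comment", "", "CC(N)=O acetamide"),
             path)
  smi <- read_smiles_file(path)
  expect_equal(unname(smi), c("CCO", "C1CCCCC1", "CC(N)=O"))
  expect_equal(names(smi)[1], "ethanol")
})

test_that("run configuration files round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  cfg <- mdp_config(element_set = c("C", "N"), max_steps = 12L,
                    allowed_ring_sizes = c(5L, 6L))
  spec <- reward_spec("single_property", properties = "qed", gamma = 0.9,
                      max_steps = 12L)
  write_run_config(path, cfg, spec, agent_args = list(heads = 4L))
  rt <- read_run_config(path)
  expect_equal(rt$config$element_set, c("C", "N"))
  expect_equal(rt$config$max_steps, 12L)
  expect_equal(rt$spec$kind, "single_property")
  expect_equal(rt$spec$gamma, 0.9)
  expect_equal(rt$agent_args$heads, 4L)
})
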