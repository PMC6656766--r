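#' Run reports
#'
#' Aggregates the terminal molecules of a run the way results tables are
#' usually reported: the top-k *unique* final molecules by score over the
#' last `window` terminal states, the fraction of generated terminal
#' molecules that sanitize, and the per-episode returns. The report is a
#' pure function of the terminal multiset (episode order within the window
#' does not matter).
#'
#' @param terminals Character vector of terminal molecules (episode order).
#' @param scores Numeric scores aligned with `terminals`.
#' @param returns Optional per-episode discounted returns.
#' @param window Use only the last `window` terminals (default 100).
#' @param k Number of top unique molecules to report.
#' @return An object of class `run_report`.
#' @export
run_report <- function(terminals, scores, returns = NULL, window = 100L, k = 3L) {
  n <- length(terminals)
  take <- seq.int(max(1L, n - window + 1L), length.out = min(window, n))
  term <- terminals[take]
  sc <- scores[take]
  keep <- !duplicated(term)
  ord <- order(sc[keep], term[keep], decreasing = c(TRUE, FALSE), method = "radix")
  top <- data.frame(smiles = term[keep][ord], score = sc[keep][ord],
                    stringsAsFactors = FALSE)
  structure(list(
    top = utils::head(top, k),
    validity = validity_fraction(term),
    n_terminals = length(term),
    terminals = term,
    scores = sc,
    returns = returns
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$n_terminals, " terminal molecules, validity ",
      sprintf("%.1f%%", 100 * x$validity), "\n", sep = "")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Fraction of molecules that sanitize
#'
#' @param smiles Character vector (empty strings count as valid states but
#'   are excluded from the denominator only if `drop_empty`).
#' @param drop_empty Drop empty molecules before measuring.
#' @return Fraction in `[0, 1]` (1 for an empty input).
#' @export
validity_fraction <- function(smiles, drop_empty = FALSE) {
  if (drop_empty) smiles <- smiles[nzchar(smiles)]
  if (length(smiles) == 0L) return(1)
  ok <- vapply(smiles, function(s) {
    if (!nzchar(s)) return(TRUE)
    !inherits(tryCatch(parse_molecule(s), error = identity), "error")
  }, logical(1))
  mean(ok)
}

# Greedy choice among candidate successors: highest raw reward, ties broken
# by lexicographically smallest canonical SMILES (deterministic everywhere).
greedy_choice <- function(acts, spec) {
  vals <- reward_value(acts$smiles, spec)
  best <- which(vals == max(vals))
  best[order(acts$smiles[best], method = "radix")][1L]
}

#' Baseline policies: random walk, greedy, epsilon-greedy
#'
#' The three reference policies. `random` picks a uniformly random valid
#' action each step; `greedy` evaluates the reward of every candidate
#' successor and takes the best (ties broken by lexicographic canonical
#' SMILES); `eps_greedy` follows `random` with probability `epsilon` and
#' `greedy` otherwise. All policies act on the same valence-constrained
#' action space, so every generated molecule is valid by construction.
#'
#' @param policy `"random"`, `"greedy"` or `"eps_greedy"`.
#' @param config An [mdp_config()].
#' @param spec A [reward_spec()]; candidate successors are scored with its
#'   raw (undiscounted) reward.
#' @param n_episodes Number of episodes to run.
#' @param seed RNG seed.
#' @param epsilon Exploration probability for `eps_greedy` (default 0.1).
#' @param window,k Report window and top-k (see [run_report()]).
#' @return A [run_report()]; its `terminals`/`scores` fields hold the raw
#'   per-episode results.
#' @export
run_baseline <- function(policy = c("random", "greedy", "eps_greedy"),
                         config, spec, n_episodes = 100L, seed = 1L,
                         epsilon = 0.1, window = 100L, k = 3L) {
  policy <- match.arg(policy)
  set.seed(seed)
  eps <- switch(policy, random = 1, greedy = 0, eps_greedy = epsilon)
  terminals <- character(n_episodes)
  scores <- numeric(n_episodes)
  returns <- numeric(n_episodes)
  for (ep in seq_len(n_episodes)) {
    s <- mol_state(config$start_molecule, 0L)
    ret <- 0
    while (!is_terminal(s, config)) {
      acts <- valid_actions(s, config)
      i <- if (eps > 0 && stats::runif(1) < eps) {
        sample.int(nrow(acts), 1L)
      } else {
        greedy_choice(acts, spec)
      }
      s <- structure(list(molecule = acts$smiles[i],
                          steps_taken = s$steps_taken + 1L),
                     class = "mol_state")
      raw <- reward_value(s$molecule, spec)
      ret <- ret + discounted_step_reward(raw, s$steps_taken, spec$gamma,
                                          config$max_steps)
    }
    terminals[ep] <- s$molecule
    scores[ep] <- reward_value(s$molecule, spec)
    returns[ep] <- ret
  }
  run_report(terminals, scores, returns, window = window, k = k)
}

# Shared training rollout machinery. `spec_for` maps an episode's start
# molecule to its reward spec (constant for ordinary training; per-episode
# for the constrained task, whose reference is the episode start).
dqn_run <- function(agent, config, spec_for, n_episodes, seed,
                    start_pool = NULL, epsilon_start = 1, epsilon_end = 0.01,
                    anneal_fraction = 1, train = TRUE, log_csv = NULL) {
  set.seed(seed)
  hp <- agent$hp
  Tmax <- config$max_steps
  terminals <- character(n_episodes)
  scores <- numeric(n_episodes)
  returns <- numeric(n_episodes)
  history <- vector("list", n_episodes)
  for (ep in seq_len(n_episodes)) {
    agent$head <- sample.int(hp$heads, 1L)
    # annealed over THIS run's episodes (a continued/phase-two run re-anneals)
    epsv <- epsilon_schedule(ep - 1L, n_episodes,
                             epsilon_start, epsilon_end, anneal_fraction)
    start <- if (is.null(start_pool)) config$start_molecule
             else start_pool[sample.int(length(start_pool), 1L)]
    spec <- spec_for(start)
    s <- mol_state(start, 0L)
    ret <- 0
    losses <- c()
    while (!is_terminal(s, config)) {
      t_next <- s$steps_taken + 1L
      acts <- valid_actions(s, config)
      # same draw pattern as select_action(), but the Q forward pass is
      # skipped entirely when the step explores
      i <- if (epsv > 0 && stats::runif(1) < epsv) {
        sample.int(nrow(acts), 1L)
      } else {
        X <- candidate_features(acts$smiles, t_next, Tmax,
                                hp$radius, hp$nbits)
        which.max(qnet_forward(agent$net, X)[, agent$head])
      }
      terminal <- t_next >= Tmax
      raw <- reward_value(acts$smiles[i], spec)
      disc <- discounted_step_reward(raw, t_next, spec$gamma, Tmax)
      s2 <- structure(list(molecule = acts$smiles[i], steps_taken = t_next),
                      class = "mol_state")
      if (train) {
        succ_bits <- list(); succ_steps <- 0L
        if (!terminal) {
          succ <- valid_actions(s2, config)
          succ_bits <- morgan_onbits(succ$smiles, hp$radius, hp$nbits)
          succ_steps <- Tmax - (t_next + 1L)
        }
        mask <- stats::runif(hp$heads) < hp$mask_prob
        act_bits <- morgan_onbits(acts$smiles[i], hp$radius, hp$nbits)[[1L]]
        store_transition(agent, make_transition(
          act_onbits = act_bits,
          act_steps = Tmax - t_next, reward = disc, terminal = terminal,
          succ_onbits = succ_bits, succ_steps = succ_steps, mask = mask))
        agent$env_steps <- agent$env_steps + 1L
        if (agent$env_steps > hp$warmup &&
            agent$env_steps %% hp$train_every == 0L) {
          l <- train_step(agent)
          if (!is.na(l)) losses <- c(losses, l)
        }
      }
      ret <- ret + disc
      s <- s2
    }
    agent$episode <- agent$episode + 1L
    terminals[ep] <- s$molecule
    scores[ep] <- reward_value(s$molecule, spec)
    returns[ep] <- ret
    history[[ep]] <- data.frame(
      episode = agent$episode, epsilon = epsv, head = agent$head,
      terminal_smiles = s$molecule, terminal_score = scores[ep],
      return_ = ret,
      mean_loss = if (length(losses)) mean(losses) else NA_real_)
  }
  history <- do.call(rbind, history)
  if (!is.null(log_csv)) utils::write.csv(history, log_csv, row.names = FALSE)
  list(terminals = terminals, scores = scores, returns = returns,
       history = history)
}

#' Train a bootstrapped DQN on the molecule MDP
#'
#' Runs `n_episodes` training episodes: each episode draws a bootstrap head,
#' rolls out epsilon-greedily over the valid actions (epsilon annealed
#' linearly from `epsilon_start` to `epsilon_end` across the run), stores
#' masked transitions in the replay buffer and takes gradient steps on the
#' masked double-Q Huber loss.
#'
#' @param config An [mdp_config()]; its horizon must match the spec's.
#' @param spec A [reward_spec()].
#' @param n_episodes Number of training episodes.
#' @param seed RNG seed (drives init, exploration, masks, head draws).
#' @param agent Optionally a pre-built [dqn_agent()] to continue training.
#' @param start_pool Optional SMILES vector; episode starts are sampled
#'   uniformly from it (otherwise `config$start_molecule` is used).
#' @param epsilon_start,epsilon_end,anneal_fraction Epsilon schedule.
#' @param window,k Report window and top-k.
#' @param log_csv Optional path for a per-episode CSV training log.
#' @param checkpoint Optional path; the final agent is checkpointed there.
#' @param ... Passed to [dqn_agent()] when no agent is supplied.
#' @return A list with `report` (a [run_report()]), `agent`, and `history`
#'   (per-episode data frame).
#' @export
train_dqn <- function(config, spec, n_episodes = 5000L, seed = 1L,
                      agent = NULL, start_pool = NULL,
                      epsilon_start = 1, epsilon_end = 0.01,
                      anneal_fraction = 1, window = 100L, k = 3L,
                      log_csv = NULL, checkpoint = NULL, ...) {
  if (!is.null(spec$max_steps) && spec$max_steps != config$max_steps)
    stop("horizon mismatch: config$max_steps = ", config$max_steps,
         " but spec$max_steps = ", spec$max_steps)
  if (is.null(agent)) agent <- dqn_agent(seed = seed, ...)
  res <- dqn_run(agent, config, function(start) spec, n_episodes, seed,
                 start_pool = start_pool, epsilon_start = epsilon_start,
                 epsilon_end = epsilon_end, anneal_fraction = anneal_fraction,
                 train = TRUE, log_csv = log_csv)
  if (!is.null(checkpoint)) save_checkpoint(agent, checkpoint)
  list(report = run_report(res$terminals, res$scores, res$returns,
                           window = window, k = k),
       agent = agent, history = res$history)
}

#' Two-phase QED optimization
#'
#' Phase one trains from the empty molecule; phase two restarts training
#' with episode starts drawn uniformly from the five highest-QED unique
#' molecules found in phase one (fewer if phase one produced fewer unique
#' molecules, with a message). The returned report merges the terminals of
#' both phases.
#'
#' @param config An [mdp_config()] (empty start molecule).
#' @param spec A QED [reward_spec()].
#' @param n_episodes_phase1,n_episodes_phase2 Episode budgets.
#' @param seed RNG seed.
#' @param agent Optional [dqn_agent()] (shared across both phases).
#' @param n_starts Size of the phase-two start pool (default 5).
#' @param ... Passed to [train_dqn()].
#' @return As [train_dqn()], plus `phase1`, `phase2` and `start_pool`.
#' @export
train_two_step_qed <- function(config, spec, n_episodes_phase1 = 2500L,
                               n_episodes_phase2 = 2500L, seed = 1L,
                               agent = NULL, n_starts = 5L, ...) {
  p1 <- train_dqn(config, spec, n_episodes = n_episodes_phase1, seed = seed,
                  agent = agent, window = n_episodes_phase1, ...)
  pool <- top_unique(p1$report$terminals, p1$report$scores, n_starts)
  if (length(pool) < n_starts)
    message("phase one produced only ", length(pool),
            " unique molecules; using all of them as phase-two starts")
  p2 <- train_dqn(config, spec, n_episodes = n_episodes_phase2,
                  seed = seed + 1L, agent = p1$agent, start_pool = pool,
                  window = n_episodes_phase2, ...)
  terminals <- c(p1$report$terminals, p2$report$terminals)
  scores <- c(p1$report$scores, p2$report$scores)
  list(report = run_report(terminals, scores, window = 100L),
       agent = p2$agent, phase1 = p1, phase2 = p2, start_pool = pool)
}

# Highest-scoring unique molecules (descending score), used for the
# phase-two start pool.
top_unique <- function(smiles, scores, k) {
  keep <- !duplicated(smiles) & nzchar(smiles)
  ord <- order(scores[keep], decreasing = TRUE)
  utils::head(smiles[keep][ord], k)
}

#' Evaluation rollouts with diversity strategies
#'
#' Rolls out a trained agent without learning. Modes: `"argmax"` follows one
#' head greedily (fully deterministic -- running it twice yields the same
#' molecule); `"per_episode_head"` draws a head uniformly each episode and
#' follows it greedily; `"softmax_q"` samples each action with probability
#' proportional to its Q-value after shifting by the minimum (Q-values may
#' be negative; an all-equal vector falls back to uniform); `"eps"` is
#' epsilon-greedy with a fixed head (`epsilon = 0` reduces to `"argmax"`).
#'
#' @param agent A trained [dqn_agent()] (or a checkpoint path).
#' @param config An [mdp_config()].
#' @param spec A [reward_spec()] used to log per-step rewards.
#' @param start_molecule Episode start (default the config's).
#' @param mode Rollout mode, see above.
#' @param n_episodes Number of episodes.
#' @param epsilon Exploration probability for `mode = "eps"`.
#' @param head Head used by `"argmax"` and `"eps"`.
#' @param seed RNG seed for the stochastic modes.
#' @return A list of episode records; each is a data frame with one row per
#'   step (`t`, `smiles`, `kind`, `q`, `raw_reward`, `disc_reward`).
#' @export
evaluate_agent <- function(agent, config, spec, start_molecule = NULL,
                           mode = c("argmax", "per_episode_head",
                                    "softmax_q", "eps"),
                           n_episodes = 1L, epsilon = 0, head = 1L,
                           seed = 1L) {
  mode <- match.arg(mode)
  if (is.character(agent)) agent <- load_checkpoint(agent)
  set.seed(seed)
  hp <- agent$hp
  Tmax <- config$max_steps
  start <- if (is.null(start_molecule)) config$start_molecule else start_molecule
  episodes <- vector("list", n_episodes)
  for (ep in seq_len(n_episodes)) {
    h <- if (mode == "per_episode_head")
      sample.int(hp$heads, 1L) else as.integer(head)
    s <- mol_state(start, 0L)
    rows <- vector("list", Tmax)
    while (!is_terminal(s, config)) {
      t_next <- s$steps_taken + 1L
      acts <- valid_actions(s, config)
      X <- candidate_features(acts$smiles, t_next, Tmax, hp$radius, hp$nbits)
      qv <- qnet_forward(agent$net, X)[, h]
      i <- switch(mode,
        argmax = ,
        per_episode_head = which.max(qv),
        eps = select_action(qv, epsilon),
        softmax_q = {
          p <- qv - min(qv)
          if (sum(p) <= 0) p <- rep(1, length(p))
          sample.int(length(p), 1L, prob = p)
        })
      raw <- reward_value(acts$smiles[i], spec)
      rows[[t_next]] <- data.frame(
        t = t_next, smiles = acts$smiles[i], kind = acts$kind[i],
        q = qv[i], raw_reward = raw,
        disc_reward = discounted_step_reward(raw, t_next, spec$gamma, Tmax),
        stringsAsFactors = FALSE)
      s <- structure(list(molecule = acts$smiles[i], steps_taken = t_next),
                     class = "mol_state")
    }
    episodes[[ep]] <- do.call(rbind, rows)
  }
  episodes
}

#' Similarity-constrained optimization experiment
#'
#' Trains one agent on the constrained reward with episode starts sampled
#' uniformly from the supplied molecules (each episode's similarity
#' reference is its own start molecule), then evaluates one deterministic
#' argmax episode per start molecule. Reported per molecule: the penalized
#' logP improvement of the final over the starting molecule and whether the
#' final molecule satisfies the similarity constraint `SIM >= delta`.
#'
#' @param start_smiles A SMILES file path or character vector of start
#'   molecules (must be non-empty).
#' @param delta Similarity threshold in `[0, 1]`.
#' @param lambda Penalty weight (default 100).
#' @param config An [mdp_config()]; conventionally horizon 20 and ring
#'   sizes 5-6 for this task.
#' @param n_episodes Training episode budget.
#' @param seed RNG seed.
#' @param agent Optional pre-built [dqn_agent()].
#' @param ... Passed to [dqn_agent()] when none is supplied.
#' @return A list with `results` (data frame: `start`, `final`,
#'   `improvement`, `similarity`, `success`), `agent`, and `history`.
#' @export
constrained_experiment <- function(start_smiles, delta = 0.6, lambda = 100,
                                   config = mdp_config(max_steps = 20L,
                                                       allowed_ring_sizes = c(5L, 6L)),
                                   n_episodes = 200L, seed = 1L,
                                   agent = NULL, ...) {
  if (length(start_smiles) == 1L && file.exists(start_smiles))
    start_smiles <- read_smiles_file(start_smiles)
  if (length(start_smiles) == 0L) stop("no start molecules supplied")
  start_smiles <- vapply(start_smiles, function(s) parse_molecule(s)$smiles,
                         character(1), USE.NAMES = FALSE)
  if (is.null(agent)) agent <- dqn_agent(seed = seed, ...)
  spec_for <- function(start) {
    reward_spec("constrained", properties = "plogp", lambda = lambda,
                delta = delta, reference = start, gamma = 0.9,
                max_steps = config$max_steps)
  }
  res <- dqn_run(agent, config, spec_for, n_episodes, seed,
                 start_pool = start_smiles)
  rows <- lapply(start_smiles, function(m0) {
    spec <- spec_for(m0)
    eps <- evaluate_agent(agent, config, spec, start_molecule = m0,
                          mode = "argmax", n_episodes = 1L, seed = seed)
    final <- eps[[1L]]$smiles[nrow(eps[[1L]])]
    data.frame(start = m0, final = final,
               improvement = penalized_logp(final) - penalized_logp(m0),
               similarity = similarity(final, m0),
               success = similarity(final, m0) >= delta,
               stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, rows), agent = agent, history = res$history)
}
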