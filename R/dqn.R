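#' Bootstrapped double-DQN agent
#'
#' Bundles the online and target Q-networks, the Adam state, a ring replay
#' buffer and the training hyperparameters into one mutable object
#' (an environment, so training functions update it in place).
#'
#' Each episode draws one of the `H` bootstrap heads uniformly and follows
#' it epsilon-greedily; each stored transition draws a Bernoulli mask over
#' heads, so every head trains on its own subset of the replay data. Targets
#' use double Q-learning: the online network picks the argmax successor, the
#' target network evaluates it. The discount is already folded into the
#' stored rewards (`gamma^(T-t)` convention), so no extra discount factor
#' appears in the target.
#'
#' The number of heads, replay capacity, batch size, target-sync cadence and
#' mask probability are engineering defaults, not quantities fixed by the
#' method; all are exposed here.
#'
#' @param input_dim Feature length (fingerprint bits + 1).
#' @param hidden Hidden-layer sizes of the shared trunk.
#' @param heads Number of bootstrap heads `H`.
#' @param replay_capacity Ring-buffer size in transitions.
#' @param batch_size Minibatch size per training step.
#' @param lr Adam learning rate.
#' @param target_sync Sync the target network every this many training steps.
#' @param warmup Environment steps before training starts.
#' @param train_every Train once per this many environment steps.
#' @param mask_prob Bernoulli probability of a head seeing a transition.
#' @param clip_norm Global-norm gradient clip (Inf to disable).
#' @param radius,nbits Fingerprint featurization parameters.
#' @param seed Seed for network initialization.
#' @return An environment of class `dqn_agent`.
#' @export
dqn_agent <- function(input_dim = 2049L, hidden = c(1024L, 512L, 128L, 32L),
                      heads = 10L, replay_capacity = 5000L, batch_size = 128L,
                      lr = 1e-4, target_sync = 20L, warmup = 50L,
                      train_every = 1L, mask_prob = 0.5, clip_norm = 10,
                      radius = 3L, nbits = 2048L, seed = 1L) {
  agent <- new.env(parent = emptyenv())
  agent$net <- qnetwork(input_dim, hidden, heads, seed = seed)
  agent$target <- agent$net
  agent$opt <- adam_init(agent$net)
  agent$hp <- list(heads = as.integer(heads),
                   replay_capacity = as.integer(replay_capacity),
                   batch_size = as.integer(batch_size), lr = lr,
                   target_sync = as.integer(target_sync),
                   warmup = as.integer(warmup),
                   train_every = as.integer(train_every),
                   mask_prob = mask_prob, clip_norm = clip_norm,
                   radius = as.integer(radius), nbits = as.integer(nbits),
                   hidden = as.integer(hidden), input_dim = as.integer(input_dim),
                   seed = as.integer(seed))
  agent$replay <- vector("list", replay_capacity)
  agent$replay_n <- 0L
  agent$replay_pos <- 0L
  agent$env_steps <- 0L
  agent$train_steps <- 0L
  agent$episode <- 0L
  agent$head <- 1L
  class(agent) <- c("dqn_agent", "environment")
  agent
}

#' @export
print.dqn_agent <- function(x, ...) {
  cat("<dqn_agent> ", paste(x$net$sizes, collapse = " -> "),
      "; replay ", x$replay_n, "/", x$hp$replay_capacity,
      "; episodes ", x$episode, "; train steps ", x$train_steps, "\n", sep = "")
  invisible(x)
}

# A replay record. act_onbits/act_steps featurize the chosen successor s';
# succ_onbits/succ_steps featurize all successors of s' (needed for the max
# in the target); reward already carries its gamma^(T-t) factor.
make_transition <- function(act_onbits, act_steps, reward, terminal,
                            succ_onbits, succ_steps, mask) {
  list(act_onbits = act_onbits, act_steps = act_steps, reward = reward,
       terminal = terminal, succ_onbits = succ_onbits,
       succ_steps = succ_steps, mask = mask)
}

store_transition <- function(agent, tr) {
  agent$replay_pos <- (agent$replay_pos %% agent$hp$replay_capacity) + 1L
  agent$replay[[agent$replay_pos]] <- tr
  agent$replay_n <- min(agent$replay_n + 1L, agent$hp$replay_capacity)
  invisible(agent)
}

#' Double Q-learning target for one transition
#'
#' Terminal transitions bootstrap nothing: the target is the stored reward.
#' Otherwise the online network selects the best successor of `s'` and the
#' target network evaluates it (decoupled selection/evaluation):
#' `y = r + Q_target(argmax_a Q_online(s', a), head)`. With
#' `target == net` this reduces to the vanilla one-network target
#' `y = r + max_a Q(s', a)`.
#'
#' @param transition A transition record (see [train_step()]).
#' @param net Online [qnetwork()].
#' @param target Target [qnetwork()].
#' @param head Head index.
#' @param nbits Fingerprint length used when the transition was stored.
#' @return The scalar target value.
#' @export
double_q_target <- function(transition, net, target, head = 1L,
                            nbits = 2048L) {
  if (isTRUE(transition$terminal) || length(transition$succ_onbits) == 0L)
    return(transition$reward)
  X <- feature_matrix(transition$succ_onbits, transition$succ_steps, nbits)
  q_on <- qnet_forward(net, X)[, head]
  best <- which.max(q_on)
  q_tg <- qnet_forward(target, X)[best, head]
  transition$reward + q_tg
}

#' One gradient step on a replay minibatch
#'
#' Samples a minibatch, computes per-head double-Q targets, and minimizes
#' the bootstrap-masked mean Huber loss with one Adam update. Each head only
#' sees transitions whose mask bit is set; an all-zero mask therefore sends
#' zero gradient to that head's private parameters. The target network is
#' re-synced every `target_sync` training steps.
#'
#' @param agent A [dqn_agent()].
#' @return The scalar loss (invisibly `NA` and no-op when the buffer holds
#'   fewer than `batch_size` transitions).
#' @export
train_step <- function(agent) {
  hp <- agent$hp
  if (agent$replay_n < hp$batch_size) {
    return(invisible(NA_real_))
  }
  idx <- sample.int(agent$replay_n, hp$batch_size)
  batch <- agent$replay[idx]
  H <- hp$heads
  n <- length(batch)

  # Predicted Q of the taken actions, all heads at once.
  Xa <- feature_matrix(lapply(batch, `[[`, "act_onbits"),
                       vapply(batch, `[[`, numeric(1), "act_steps"),
                       hp$nbits)
  fwd <- qnet_forward(agent$net, Xa, cache = TRUE)
  pred <- fwd$out

  # Targets: stack every successor of every s' into one matrix, forward
  # through both networks once, then take grouped argmax/eval per head.
  y <- matrix(NA_real_, n, H)
  counts <- vapply(batch, function(tr)
    if (isTRUE(tr$terminal)) 0L else length(tr$succ_onbits), integer(1))
  live <- which(counts > 0L)
  for (i in which(counts == 0L)) y[i, ] <- batch[[i]]$reward
  if (length(live)) {
    all_bits <- unlist(lapply(batch[live], `[[`, "succ_onbits"),
                       recursive = FALSE)
    all_steps <- unlist(lapply(batch[live], function(tr)
      rep_len(tr$succ_steps, length(tr$succ_onbits))))
    Xs <- feature_matrix(all_bits, all_steps, hp$nbits)
    q_on <- qnet_forward(agent$net, Xs)
    # per (transition, head) argmax row under the online network
    sel_rows <- matrix(0L, length(live), H)
    offset <- 0L
    for (j in seq_along(live)) {
      rows <- offset + seq_len(counts[live[j]])
      sel <- max.col(t(q_on[rows, , drop = FALSE]), ties.method = "first")
      sel_rows[j, ] <- rows[sel]
      offset <- offset + counts[live[j]]
    }
    # evaluate the target network only on the selected rows
    uniq <- sort(unique(as.integer(sel_rows)))
    q_tg <- qnet_forward(agent$target, Xs[uniq, , drop = FALSE])
    pos <- match(as.integer(sel_rows), uniq)
    for (j in seq_along(live)) {
      y[live[j], ] <- batch[[live[j]]]$reward +
        q_tg[cbind(pos[(seq_len(H) - 1L) * length(live) + j], seq_len(H))]
    }
  }

  mask <- do.call(rbind, lapply(batch, `[[`, "mask")) * 1
  denom <- max(1, sum(mask))
  resid <- y - pred
  loss <- sum(mask * huber_loss(resid)) / denom
  dOut <- -huber_grad(resid) * mask / denom
  grads <- qnet_backward(agent$net, fwd, dOut)
  upd <- adam_update(agent$net, agent$opt, grads, lr = hp$lr,
                     clip_norm = hp$clip_norm)
  agent$net <- upd$net
  agent$opt <- upd$opt
  agent$train_steps <- agent$train_steps + 1L
  if (agent$train_steps %% hp$target_sync == 0L) agent$target <- agent$net
  loss
}

#' Save / load agent checkpoints
#'
#' Checkpoints hold both networks, the optimizer state, counters and the
#' hyperparameters, so training and evaluation can resume exactly.
#'
#' @param agent A [dqn_agent()].
#' @param path Checkpoint file path.
#' @return `save_checkpoint` invisibly returns `path`; `load_checkpoint`
#'   returns a restored [dqn_agent()].
#' @export
save_checkpoint <- function(agent, path) {
  saveRDS(list(net = agent$net, target = agent$target, opt = agent$opt,
               hp = agent$hp, env_steps = agent$env_steps,
               train_steps = agent$train_steps, episode = agent$episode),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  st <- tryCatch(suppressWarnings(readRDS(path)), error = function(e)
    stop("corrupt or unreadable checkpoint: ", path))
  hp <- st$hp
  agent <- do.call(dqn_agent, hp[c("heads", "replay_capacity", "batch_size",
                                   "lr", "target_sync", "warmup", "train_every",
                                   "mask_prob", "clip_norm", "radius", "nbits",
                                   "hidden", "input_dim", "seed")])
  agent$net <- st$net
  agent$target <- st$target
  agent$opt <- st$opt
  agent$env_steps <- st$env_steps
  agent$train_steps <- st$train_steps
  agent$episode <- st$episode
  agent
}
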