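#' Per-action Q-value map of a state
#'
#' Scores every valid action of a state with one head of a trained agent and
#' min-max rescales the raw Q-values to `[0, 1]` for visualization (the
#' rescaling is a monotone transform, so the ordering of actions is
#' preserved; when all raw values coincide they all map to 1 by convention,
#' with a message). The chosen action is the argmax of the *raw* values, so
#' it matches what [select_action()] returns at `epsilon = 0` on the same
#' head.
#'
#' @param state A non-terminal [mol_state()].
#' @param agent A trained [dqn_agent()].
#' @param config An [mdp_config()].
#' @param head Head index, or `"mean"` to average the Q-values of all heads.
#' @return An object of class `action_value_map`: data frame `actions`
#'   (`kind`, `smiles`, `q`, `q_scaled`) plus `chosen`, the argmax row index.
#' @export
action_value_map <- function(state, agent, config, head = 1L) {
  if (is_terminal(state, config))
    stop("cannot map actions of a terminal state")
  hp <- agent$hp
  acts <- valid_actions(state, config)
  X <- candidate_features(acts$smiles, state$steps_taken + 1L,
                          config$max_steps, hp$radius, hp$nbits)
  qmat <- qnet_forward(agent$net, X)
  q <- if (identical(head, "mean")) rowMeans(qmat) else qmat[, head]
  rng <- range(q)
  if (rng[2] > rng[1]) {
    q_scaled <- (q - rng[1]) / (rng[2] - rng[1])
  } else {
    message("all Q-values equal; rescaled map set to 1")
    q_scaled <- rep(1, length(q))
  }
  out <- acts
  out$q <- q
  out$q_scaled <- q_scaled
  structure(list(actions = out, chosen = which.max(q)),
            class = "action_value_map")
}

#' @export
print.action_value_map <- function(x, ...) {
  cat("<action_value_map> ", nrow(x$actions), " actions, chosen #",
      x$chosen, " (", x$actions$smiles[x$chosen], ")\n", sep = "")
  invisible(x)
}

#' Export an action-value map as JSON
#' @param avm An [action_value_map()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_action_value_map <- function(avm, path) {
  jsonlite::write_json(list(actions = avm$actions, chosen = avm$chosen),
                       path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Per-step property trace of an episode
#'
#' Follows one property along a trajectory: the value after every step, the
#' per-step delta, and the total improvement (final minus initial, which
#' telescopes to the sum of the deltas). Steps that decrease the property
#' are flagged -- a trained Q-policy may deliberately take such steps when
#' they lead to higher future rewards.
#'
#' @param episode An episode record from [evaluate_agent()] (data frame with
#'   a `smiles` column, one row per step).
#' @param property Property name (see [reward_value()] property names) or a
#'   function of a SMILES vector.
#' @param start_molecule The molecule before the first step (default empty).
#' @return An object of class `trajectory_summary`: data frame `steps`
#'   (`t`, `smiles`, `value`, `delta`, `decreasing`) plus `total` and the
#'   initial/final values.
#' @export
trajectory_summary <- function(episode, property = "qed",
                               start_molecule = "") {
  fn <- if (is.function(property)) property
        else function(s) property_value(property, s)
  v0 <- fn(start_molecule)
  values <- fn(episode$smiles)
  delta <- diff(c(v0, values))
  steps <- data.frame(t = seq_along(values), smiles = episode$smiles,
                      value = values, delta = delta,
                      decreasing = delta < 0, stringsAsFactors = FALSE)
  structure(list(steps = steps, initial = v0,
                 final = values[length(values)],
                 total = values[length(values)] - v0),
            class = "trajectory_summary")
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("<trajectory_summary> ", nrow(x$steps), " steps, ",
      sprintf("%.4f -> %.4f (total %+0.4f), %d decreasing step(s)\n",
              x$initial, x$final, x$total, sum(x$steps$decreasing)), sep = "")
  invisible(x)
}

#' Write a trajectory summary as CSV
#' @param summary A [trajectory_summary()].
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_trajectory_csv <- function(summary, path) {
  utils::write.csv(summary$steps, path, row.names = FALSE)
  invisible(path)
}
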