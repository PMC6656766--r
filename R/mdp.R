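#' Configuration of the molecule-editing MDP
#'
#' Defines the environment: which elements may be added, the episode horizon
#' `T`, which ring sizes may be formed by bond addition, and which action
#' families are enabled. The defaults match the single-property optimization
#' setting (elements C/O/N, ring sizes 5-7); constrained and multi-objective
#' experiments conventionally restrict rings to sizes 5-6.
#'
#' @param element_set Character vector of element symbols available for atom
#'   addition.
#' @param max_steps Positive integer horizon `T`; states with `t == T` are
#'   terminal.
#' @param allowed_ring_sizes Integer subset of 3:8; a bond addition that
#'   creates a ring is kept only if every SSSR ring through the new bond has
#'   a size in this set.
#' @param allow_no_modification Offer a "leave the molecule unchanged" action
#'   on non-empty states.
#' @param allow_atom_addition,allow_bond_addition,allow_bond_removal Enable
#'   the three edit families.
#' @param start_molecule Canonical SMILES of the episode start (`""` = empty
#'   molecule).
#' @param bond_between_rings Ring heuristic for bond addition: `"forbid-both"`
#'   (default) excludes a pair only when both endpoints are in rings;
#'   `"forbid-any"` excludes pairs with at least one ring endpoint.
#' @return An object of class `mdp_config`.
#' @export
mdp_config <- function(element_set = c("C", "O", "N"),
                       max_steps = 40L,
                       allowed_ring_sizes = c(5L, 6L, 7L),
                       allow_no_modification = TRUE,
                       allow_atom_addition = TRUE,
                       allow_bond_addition = TRUE,
                       allow_bond_removal = TRUE,
                       start_molecule = "",
                       bond_between_rings = c("forbid-both", "forbid-any")) {
  bond_between_rings <- match.arg(bond_between_rings)
  element_set <- as.character(element_set)
  allowed_ring_sizes <- sort(unique(as.integer(allowed_ring_sizes)))
  max_steps <- as.integer(max_steps)
  if (max_steps < 1L) stop("max_steps must be a positive integer")
  if (allow_atom_addition && length(element_set) == 0L)
    stop("element_set must be non-empty when atom addition is enabled")
  if (length(allowed_ring_sizes) && !all(allowed_ring_sizes %in% 3:8))
    stop("allowed_ring_sizes must be a subset of 3:8")
  cfg <- structure(list(
    element_set = element_set,
    max_steps = max_steps,
    allowed_ring_sizes = allowed_ring_sizes,
    allow_no_modification = isTRUE(allow_no_modification),
    allow_atom_addition = isTRUE(allow_atom_addition),
    allow_bond_addition = isTRUE(allow_bond_addition),
    allow_bond_removal = isTRUE(allow_bond_removal),
    start_molecule = start_molecule,
    bond_between_rings = bond_between_rings
  ), class = "mdp_config")
  cfg
}

config_key <- function(config) {
  paste(paste(config$element_set, collapse = ","),
        paste(config$allowed_ring_sizes, collapse = ","),
        config$allow_no_modification, config$allow_atom_addition,
        config$allow_bond_addition, config$allow_bond_removal,
        config$bond_between_rings, sep = "|")
}

#' MDP state: a molecule plus a step counter
#'
#' @param molecule Canonical SMILES (`""` for the empty molecule).
#' @param steps_taken Non-negative integer `t`.
#' @return An object of class `mol_state`.
#' @export
mol_state <- function(molecule = "", steps_taken = 0L) {
  steps_taken <- as.integer(steps_taken)
  stopifnot(is.character(molecule), length(molecule) == 1L, steps_taken >= 0L)
  if (nzchar(molecule)) molecule <- parse_molecule(molecule)$smiles
  structure(list(molecule = molecule, steps_taken = steps_taken),
            class = "mol_state")
}

#' @export
print.mol_state <- function(x, ...) {
  cat("<mol_state> ", if (nzchar(x$molecule)) x$molecule else "(empty)",
      "  t=", x$steps_taken, "\n", sep = "")
  invisible(x)
}

#' Is a state terminal under a configuration?
#' @param state A [mol_state()].
#' @param config An [mdp_config()].
#' @return `TRUE` iff `steps_taken == max_steps`.
#' @export
is_terminal <- function(state, config) {
  state$steps_taken >= config$max_steps
}

action_set <- function(kind, smiles) {
  keep <- !duplicated(smiles)
  data.frame(kind = kind[keep], smiles = smiles[keep], stringsAsFactors = FALSE)
}

# Default valences used only to prune edits before the sanitization check;
# the backend's sanitization remains the arbiter of validity.
ELEMENT_VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L, P = 5L, S = 6L,
                     Cl = 1L, Br = 1L, I = 1L, B = 3L)

max_order_for <- function(el) {
  v <- ELEMENT_VALENCE[el]
  v[is.na(v)] <- 3L
  pmin(unname(v), 3L)
}

#' Enumerate atom-addition actions
#'
#' One action per (attachment atom with free valence, element, bond order)
#' triple whose product sanitizes. Hydrogens are implicit: an addition
#' replaces implicit hydrogens on the attachment atom. All valence-allowed
#' bond orders count as separate edits, but actions are identified by their
#' product, so symmetry-equivalent edits collapse to one action. On the
#' empty molecule the actions are the single-atom molecules of the element
#' set.
#'
#' @param molecule SMILES of the current molecule (`""` for empty).
#' @param config An [mdp_config()].
#' @return A data frame of actions with columns `kind` and `smiles` (the
#'   canonical successor molecule).
#' @export
enumerate_atom_additions <- function(molecule, config) {
  if (!nzchar(molecule)) {
    return(action_set(rep("atom_addition", length(config$element_set)),
                      seed_atoms(config$element_set)))
  }
  info <- parse_molecule(molecule)
  atoms <- info$atoms[info$atoms$fv > 0L, , drop = FALSE]
  if (nrow(atoms) == 0L)
    return(action_set(character(0), character(0)))
  grid <- expand.grid(atom = atoms$i, el = config$element_set,
                      order = 1:3, stringsAsFactors = FALSE)
  fv <- atoms$fv[match(grid$atom, atoms$i)]
  grid <- grid[grid$order <= pmin(fv, max_order_for(grid$el)), , drop = FALSE]
  if (nrow(grid) == 0L)
    return(action_set(character(0), character(0)))
  edits <- data.frame(op = "addatom", atom = grid$atom, el = grid$el,
                      order = grid$order, stringsAsFactors = FALSE)
  res <- apply_edits(info$smiles, edits)
  ok <- res$ok & !is.na(res$smiles)
  action_set(rep("atom_addition", sum(ok)), res$smiles[ok])
}

#' Enumerate bond-addition actions
#'
#' Creates a new bond or increases an existing bond's order (by one or two)
#' between two atoms with free valence. Heuristics: pairs whose endpoints
#' are both in rings are excluded (strain heuristic; configurable via
#' `bond_between_rings`), aromatic bonds are never modified, and a new bond
#' is kept only if every ring it closes has an allowed size. Every product
#' sanitizes.
#'
#' @inheritParams enumerate_atom_additions
#' @return A data frame of actions (`kind`, `smiles`).
#' @export
enumerate_bond_additions <- function(molecule, config) {
  empty <- action_set(character(0), character(0))
  if (!nzchar(molecule)) return(empty)
  info <- parse_molecule(molecule)
  atoms <- info$atoms[info$atoms$fv > 0L, , drop = FALSE]
  if (nrow(atoms) < 2L) return(empty)
  pairs <- utils::combn(seq_len(nrow(atoms)), 2L)
  a1 <- atoms[pairs[1L, ], ]
  a2 <- atoms[pairs[2L, ], ]
  keep <- if (config$bond_between_rings == "forbid-both")
    !(a1$ring & a2$ring) else !(a1$ring | a2$ring)
  a1 <- a1[keep, , drop = FALSE]; a2 <- a2[keep, , drop = FALSE]
  if (nrow(a1) == 0L) return(empty)

  bonds <- info$bonds
  bkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
  border <- setNames(ifelse(bonds$arom, NA_integer_, bonds$order),
                     bkey(bonds$a, bonds$b))
  cur <- unname(border[bkey(a1$i, a2$i)])
  exists <- bkey(a1$i, a2$i) %in% names(border)
  arom <- exists & is.na(cur)
  cur[!exists] <- 0L

  rows <- list()
  fvmin <- pmin(a1$fv, a2$fv)
  for (delta in 1:3) {
    new_order <- cur + delta
    ok <- !arom & new_order <= 3L & delta <= fvmin &
      (cur > 0L | delta == new_order) &     # new bonds: any order 1..3
      (cur == 0L | delta <= 2L)             # increases: by one or two only
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      op = "bond", a = a1$i[ok], b = a2$i[ok], order = new_order[ok],
      new_bond = cur[ok] == 0L, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  edits <- do.call(rbind, rows)
  res <- apply_edits(info$smiles, edits[c("op", "a", "b", "order")])
  ok <- res$ok & !is.na(res$smiles)
  if (length(config$allowed_ring_sizes)) {
    ring_ok <- vapply(res$rings, function(rs)
      length(rs) == 0L || all(rs %in% config$allowed_ring_sizes), logical(1))
    ok <- ok & ring_ok
  }
  action_set(rep("bond_addition", sum(ok)), res$smiles[ok])
}

#' Enumerate bond-removal actions
#'
#' Decreases the order of an existing non-aromatic bond by one, two or three
#' as applicable. A complete removal is kept only when the product has zero
#' or one disconnected atom; a single disconnected atom is deleted from the
#' product, so no multi-fragment molecule is ever emitted.
#'
#' @param molecule SMILES of the current molecule (`""` for empty).
#' @return A data frame of actions (`kind`, `smiles`).
#' @export
enumerate_bond_removals <- function(molecule) {
  empty <- action_set(character(0), character(0))
  if (!nzchar(molecule)) return(empty)
  info <- parse_molecule(molecule)
  bonds <- info$bonds[!info$bonds$arom, , drop = FALSE]
  if (nrow(bonds) == 0L) return(empty)
  rows <- list()
  for (delta in 1:3) {
    ok <- bonds$order >= delta
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      op = "bond", a = bonds$a[ok], b = bonds$b[ok],
      order = bonds$order[ok] - delta, stringsAsFactors = FALSE)
  }
  edits <- do.call(rbind, rows)
  res <- apply_edits(info$smiles, edits)
  ok <- res$ok & !is.na(res$smiles)
  action_set(rep("bond_removal", sum(ok)), res$smiles[ok])
}

#' All valid actions of a state
#'
#' The union of the enabled edit families plus, on non-empty molecules, the
#' "no modification" action. Actions are deduplicated by canonical successor
#' SMILES with family precedence atom addition > bond addition > bond
#' removal > no modification. The set is never empty on a reachable
#' non-terminal state, and every member's product sanitizes.
#'
#' @param state A [mol_state()] (non-terminal).
#' @param config An [mdp_config()].
#' @return A data frame of actions (`kind`, `smiles`).
#' @export
valid_actions <- function(state, config) {
  if (is_terminal(state, config))
    stop("valid_actions() called on a terminal state (t = ",
         state$steps_taken, ")")
  molecule <- state$molecule
  cache <- cache_env("action_cache")
  key <- paste0(config_key(config), "||", molecule)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  parts <- list()
  if (config$allow_atom_addition)
    parts$atom <- enumerate_atom_additions(molecule, config)
  if (config$allow_bond_addition)
    parts$bond <- enumerate_bond_additions(molecule, config)
  if (config$allow_bond_removal)
    parts$removal <- enumerate_bond_removals(molecule)
  if (config$allow_no_modification && nzchar(molecule))
    parts$noop <- data.frame(kind = "no_modification",
                             smiles = parse_molecule(molecule)$smiles,
                             stringsAsFactors = FALSE)
  out <- do.call(rbind, unname(parts))
  if (is.null(out)) out <- action_set(character(0), character(0))
  out <- out[!duplicated(out$smiles), , drop = FALSE]
  rownames(out) <- NULL
  cache[[key]] <- out
  out
}

#' Deterministic MDP transition
#'
#' Applies an action to a state: the successor is the action's product
#' molecule with the step counter incremented. The transition is a pure
#' function (probability 1); identical inputs give identical outputs.
#'
#' @param state A non-terminal [mol_state()].
#' @param action Either one row of the [valid_actions()] data frame, a list
#'   with a `smiles` element, or a SMILES string; it must be a member of the
#'   state's valid action set.
#' @param config An [mdp_config()].
#' @return The successor [mol_state()].
#' @export
mdp_step <- function(state, action, config) {
  if (is_terminal(state, config))
    stop("cannot step a terminal state (t = ", state$steps_taken, ")")
  smiles <- if (is.character(action)) action else action$smiles
  stopifnot(is.character(smiles), length(smiles) == 1L)
  acts <- valid_actions(state, config)
  if (!smiles %in% acts$smiles)
    stop("action ", deparse(smiles), " is not valid in this state")
  structure(list(molecule = smiles, steps_taken = state$steps_taken + 1L),
            class = "mol_state")
}

#' Export an action set as JSON lines
#'
#' Writes one `{"kind": ..., "result_smiles": ...}` object per line.
#'
#' @param actions A data frame from [valid_actions()].
#' @param path Output file path.
#' @return Invisibly `path`.
#' @export
write_actions_jsonl <- function(actions, path) {
  lines <- vapply(seq_len(nrow(actions)), function(i) {
    jsonlite::toJSON(list(kind = actions$kind[i],
                          result_smiles = actions$smiles[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
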