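#' Featurize an MDP state for the Q-network
#'
#' A state (molecule, t) is encoded as the binary Morgan fingerprint of the
#' molecule (radius 3, 2048 bits) with the number of steps remaining in the
#' episode, `T - t`, appended as one extra numeric slot -- 2049 features in
#' total. The empty molecule has the all-zero fingerprint. Encoding is
#' deterministic: two calls on identical inputs are bit-identical, and for a
#' fixed molecule the encoding is injective in `t`.
#'
#' @param state A [mol_state()].
#' @param max_steps Horizon `T`.
#' @param radius,nbits Fingerprint parameters (defaults: radius 3, 2048 bits).
#' @return An object of class `state_features`: list with `onbits` (1-based
#'   fingerprint on-bit indices), `steps_remaining`, and `nbits`.
#' @export
featurize <- function(state, max_steps, radius = 3L, nbits = 2048L) {
  stopifnot(state$steps_taken <= max_steps)
  onbits <- if (nzchar(state$molecule))
    morgan_onbits(state$molecule, radius, nbits)[[1L]] else integer(0)
  structure(list(onbits = onbits,
                 steps_remaining = as.integer(max_steps - state$steps_taken),
                 nbits = as.integer(nbits)),
            class = "state_features")
}

#' @export
print.state_features <- function(x, ...) {
  cat("<state_features> ", length(x$onbits), " on-bits / ", x$nbits,
      ", steps remaining ", x$steps_remaining, "\n", sep = "")
  invisible(x)
}

#' Dense numeric vector form of state features
#' @param features A `state_features` object.
#' @return Numeric vector of length `nbits + 1`.
#' @export
feature_vector <- function(features) {
  v <- numeric(features$nbits + 1L)
  v[features$onbits] <- 1
  v[features$nbits + 1L] <- features$steps_remaining
  v
}

# Sparse feature matrix for a batch of candidate states: one row per
# molecule, 2048 fingerprint columns plus the steps-remaining column.
# `onbits_list` holds 1-based on-bit indices; `steps_remaining` is recycled.
feature_matrix <- function(onbits_list, steps_remaining, nbits = 2048L) {
  n <- length(onbits_list)
  steps_remaining <- rep_len(steps_remaining, n)
  lens <- lengths(onbits_list)
  i <- c(rep.int(seq_len(n), lens), seq_len(n))
  j <- c(unlist(onbits_list, use.names = FALSE), rep.int(nbits + 1L, n))
  x <- c(rep.int(1, sum(lens)), as.numeric(steps_remaining))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, nbits + 1L))
}

# Feature matrix for a set of candidate successor molecules observed at
# step t (so their steps-remaining slot is T - t).
candidate_features <- function(smiles, steps_taken, max_steps,
                               radius = 3L, nbits = 2048L) {
  onbits <- morgan_onbits(smiles, radius, nbits)
  feature_matrix(onbits, max_steps - steps_taken, nbits)
}

#' Dump fingerprint on-bit indices as JSON (debug aid)
#' @param features A `state_features` object.
#' @return A JSON string with the on-bit indices and steps remaining.
#' @export
features_json <- function(features) {
  as.character(jsonlite::toJSON(list(onbits = features$onbits,
                                     steps_remaining = features$steps_remaining),
                                auto_unbox = TRUE))
}
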