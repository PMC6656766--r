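#' Declarative reward specification
#'
#' Describes how a state is scored: a single molecular property, a
#' scalarized vector of properties, a similarity-constrained objective, or a
#' property-range target. The spec also owns the discount `gamma` and the
#' horizon `T` used by the step-discounting convention.
#'
#' @param kind One of `"single_property"`, `"multi_objective"`,
#'   `"constrained"`, `"range_target"`.
#' @param properties Character vector of property names. Known names:
#'   `"plogp"` (penalized logP), `"qed"`, `"logp"`, `"sa"`, `"similarity"`
#'   (Tanimoto to `reference`).
#' @param weights Numeric weight vector `w` (multi-objective), same length as
#'   `properties`.
#' @param lambda Penalty coefficient for the constrained reward (default 100).
#' @param delta Similarity threshold in `[0, 1]` for the constrained reward.
#' @param reference Reference molecule SMILES for similarity-based rewards.
#' @param range Numeric `c(lo, hi)` for the range-target reward.
#' @param gamma Discount in `(0, 1]`; the reward at step `t` carries the
#'   factor `gamma^(T - t)` so the final state is rewarded most heavily.
#' @param max_steps Horizon `T` (copy of the MDP config's horizon).
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(kind = c("single_property", "multi_objective",
                                 "constrained", "range_target"),
                        properties = "plogp",
                        weights = NULL,
                        lambda = 100,
                        delta = 0.6,
                        reference = NULL,
                        range = NULL,
                        gamma = 0.9,
                        max_steps = 40L) {
  kind <- match.arg(kind)
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (kind == "multi_objective") {
    if (is.null(weights)) stop("multi_objective reward needs weights")
    if (length(weights) != length(properties))
      stop("weights and properties must have the same length")
  }
  if (kind == "constrained") {
    if (is.null(reference) || !nzchar(reference))
      stop("constrained reward needs a reference molecule")
    if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
    reference <- parse_molecule(reference)$smiles
  }
  if (kind == "range_target") {
    if (is.null(range) || length(range) != 2L)
      stop("range_target reward needs range = c(lo, hi)")
    if (range[1] > range[2]) stop("inverted target range")
  }
  if (any(properties == "similarity") && is.null(reference))
    stop("similarity property needs a reference molecule")
  if (!is.null(reference)) reference <- parse_molecule(reference)$smiles
  structure(list(kind = kind, properties = properties,
                 weights = as.numeric(weights), lambda = lambda,
                 delta = delta, reference = reference, range = range,
                 gamma = gamma, max_steps = as.integer(max_steps)),
            class = "reward_spec")
}

#' Penalized logP
#'
#' The octanol-water partition coefficient minus the synthetic-accessibility
#' score minus a large-ring penalty, unstandardized. The default penalty is
#' `max(0, largest_ring_size - 6)`; `cycle_mode = "count"` instead subtracts
#' the number of rings with more than six atoms (the literal "number of long
#' cycles" reading). The empty molecule scores 0 by convention.
#'
#' @param smiles Character vector of SMILES.
#' @param cycle_mode `"largest_ring"` (default) or `"count"`.
#' @return Numeric vector of penalized logP values.
#' @export
penalized_logp <- function(smiles, cycle_mode = c("largest_ring", "count")) {
  cycle_mode <- match.arg(cycle_mode)
  out <- numeric(length(smiles))
  live <- nzchar(smiles)
  if (any(live)) {
    p <- mol_props(smiles[live], c("logp", "sa", "maxring", "nring_gt6"))
    pen <- if (cycle_mode == "largest_ring") pmax(0, p$maxring - 6) else p$nring_gt6
    out[live] <- p$logp - p$sa - pen
  }
  out
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' The standard QED desirability score in `[0, 1]`; the empty molecule
#' scores 0 by convention.
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of QED values.
#' @export
qed <- function(smiles) {
  out <- numeric(length(smiles))
  live <- nzchar(smiles)
  if (any(live)) out[live] <- mol_props(smiles[live], "qed")$qed
  out
}

#' Tanimoto similarity between Morgan fingerprints
#'
#' `|A intersect B| / |A union B|` over the on-bit sets of radius-2 hashed
#' Morgan fingerprints (the set arithmetic is done in R on the backend's
#' on-bit indices). Symmetric; the empty molecule has similarity 0 to any
#' non-empty reference.
#'
#' @param smiles Character vector of SMILES.
#' @param reference A single non-empty reference SMILES.
#' @param radius,nbits Fingerprint parameters (radius 2 by convention for
#'   similarity; 2048 bits).
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
similarity <- function(smiles, reference, radius = 2L, nbits = 2048L) {
  stopifnot(is.character(reference), length(reference) == 1L, nzchar(reference))
  ref_bits <- morgan_onbits(reference, radius, nbits)[[1L]]
  bits <- morgan_onbits(smiles, radius, nbits)
  vapply(seq_along(smiles), function(i) {
    if (!nzchar(smiles[i])) return(0)
    b <- bits[[i]]
    inter <- length(intersect(b, ref_bits))
    uni <- length(b) + length(ref_bits) - inter
    if (uni == 0L) return(0)
    inter / uni
  }, numeric(1))
}

#' Scalarize a reward vector
#'
#' The dot product `w' r` collapsing a k-objective reward vector to a scalar;
#' exactly linear in both arguments.
#'
#' @param r_vec Numeric reward vector.
#' @param w Numeric weight vector of the same length.
#' @return A single number.
#' @export
scalarize <- function(r_vec, w) {
  if (length(r_vec) != length(w))
    stop("reward vector and weight vector lengths differ (",
         length(r_vec), " vs ", length(w), ")")
  sum(as.numeric(r_vec) * as.numeric(w))
}

#' Similarity-constrained reward
#'
#' `penalized_logp(m) - lambda * (delta - SIM(m, m0))` when the Tanimoto
#' similarity to the reference falls below the threshold `delta`, and plain
#' `penalized_logp(m)` otherwise. The two branches agree at `SIM == delta`
#' (the boundary belongs to the unpenalized branch), so the reward is
#' continuous in the similarity.
#'
#' @param smiles Character vector of SMILES.
#' @param spec A [reward_spec()] with `kind = "constrained"` (owns `lambda`,
#'   `delta` and the reference molecule).
#' @return Numeric vector of rewards.
#' @export
constrained_reward <- function(smiles, spec) {
  if (!identical(spec$kind, "constrained"))
    stop("spec$kind must be 'constrained'")
  if (is.null(spec$reference)) stop("constrained reward needs spec$reference")
  base <- penalized_logp(smiles)
  sim <- similarity(smiles, spec$reference)
  ifelse(sim < spec$delta, base - spec$lambda * (spec$delta - sim), base)
}

#' Step-discounted reward
#'
#' The package's discounting convention weights the reward at step `t` by
#' `gamma^(T - t)`: the terminal state's factor is 1, so the final molecule
#' is rewarded most heavily. This factor is folded into the stored reward;
#' no additional discount appears in the Q-learning target.
#'
#' @param raw Undiscounted reward value(s).
#' @param t Step index (0 to `T`), vectorized.
#' @param gamma Discount in `(0, 1]`.
#' @param max_steps Horizon `T`.
#' @return `raw * gamma^(T - t)`.
#' @export
discounted_step_reward <- function(raw, t, gamma, max_steps) {
  if (any(t > max_steps)) stop("step index exceeds the horizon")
  if (any(t < 0)) stop("negative step index")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  raw * gamma^(max_steps - t)
}

#' Relative QED improvement
#'
#' `(QED(m) - QED(m0)) / (1 - QED(m0))`: the achieved fraction of the largest
#' possible QED improvement over the starting molecule. Equals 0 when QED is
#' unchanged and 1 when QED reaches its maximum.
#'
#' @param smiles Character vector of optimized molecules.
#' @param reference The starting molecule `m0` (must have QED < 1).
#' @return Numeric vector of relative improvements.
#' @export
relative_improvement <- function(smiles, reference) {
  q0 <- qed(reference)
  if (q0 >= 1) stop("reference molecule has QED 1; relative improvement undefined")
  (qed(smiles) - q0) / (1 - q0)
}

#' Range-targeting reward
#'
#' The negative absolute distance from a property value to the target
#' interval `[lo, hi]`: 0 (the maximum) inside the interval, and decreasing
#' linearly with the distance outside it.
#'
#' @param smiles Character vector of SMILES.
#' @param spec A [reward_spec()] with `kind = "range_target"`; the targeted
#'   property is `spec$properties[1]`.
#' @return Numeric vector of rewards (all `<= 0`).
#' @export
range_target_reward <- function(smiles, spec) {
  if (!identical(spec$kind, "range_target"))
    stop("spec$kind must be 'range_target'")
  lo <- spec$range[1]; hi <- spec$range[2]
  if (lo > hi) stop("inverted target range")
  value <- property_value(spec$properties[1], smiles, spec)
  -pmax(0, pmax(lo - value, value - hi))
}

# Resolve a property name to values for a vector of molecules.
property_value <- function(name, smiles, spec = NULL) {
  switch(name,
    plogp = penalized_logp(smiles),
    qed = qed(smiles),
    logp = {
      out <- numeric(length(smiles)); live <- nzchar(smiles)
      if (any(live)) out[live] <- mol_props(smiles[live], "logp")$logp
      out
    },
    sa = {
      out <- numeric(length(smiles)); live <- nzchar(smiles)
      if (any(live)) out[live] <- mol_props(smiles[live], "sa")$sa
      out
    },
    similarity = similarity(smiles, spec$reference),
    stop("unknown property: ", name)
  )
}

#' Evaluate a reward specification on molecules
#'
#' Dispatches on the spec's kind: the single property value, the scalarized
#' `w' r` combination, the similarity-constrained piecewise reward, or the
#' range-target distance reward. This is the undiscounted ("raw") reward;
#' training applies [discounted_step_reward()] on top.
#'
#' @param smiles Character vector of SMILES.
#' @param spec A [reward_spec()].
#' @return Numeric vector of rewards.
#' @export
reward_value <- function(smiles, spec) {
  switch(spec$kind,
    single_property = property_value(spec$properties[1], smiles, spec),
    multi_objective = {
      mat <- vapply(spec$properties, property_value, numeric(length(smiles)),
                    smiles = smiles, spec = spec)
      if (length(smiles) == 1L) mat <- matrix(mat, nrow = 1L)
      as.numeric(mat %*% spec$weights)
    },
    constrained = constrained_reward(smiles, spec),
    range_target = range_target_reward(smiles, spec)
  )
}
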