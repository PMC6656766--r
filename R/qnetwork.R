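#' Multi-head Q-network
#'
#' A fully-connected rectifier network scoring featurized candidate successor
#' states: input 2049 (fingerprint plus steps remaining), hidden sizes
#' `[1024, 512, 128, 32]` by default, and one linear output per bootstrap
#' head on top of the shared trunk. Because the action set of a molecule is
#' variable, actions are scored through the state they produce
#' (successor-state parameterization): `Q(s, a) = net(features(s'))`.
#'
#' No deep-learning framework is available to this package, so the network,
#' its backward pass and the Adam optimizer are implemented directly with
#' (sparse) matrix algebra.
#'
#' @param input_dim Number of input features (2049).
#' @param hidden Integer vector of hidden-layer sizes.
#' @param heads Number of bootstrap heads `H` (output dimension).
#' @param seed Integer seed for He-style random initialization.
#' @return An object of class `qnetwork`: list of weight matrices `W`,
#'   bias vectors `b`, and the shape spec.
#' @export
qnetwork <- function(input_dim = 2049L, hidden = c(1024L, 512L, 128L, 32L),
                     heads = 10L, seed = 1L) {
  sizes <- c(input_dim, hidden, heads)
  rng <- local({ set.seed(seed); lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / fan_in)),
           nrow = sizes[l], ncol = sizes[l + 1L])
  })})
  structure(list(
    W = rng,
    b = lapply(sizes[-1L], function(n) numeric(n)),
    sizes = sizes, heads = as.integer(heads), input_dim = as.integer(input_dim)
  ), class = "qnetwork")
}

#' @export
print.qnetwork <- function(x, ...) {
  cat("<qnetwork> ", paste(x$sizes, collapse = " -> "),
      " (", x$heads, " heads)\n", sep = "")
  invisible(x)
}

# Forward pass. X: n x input_dim matrix (dense or dgCMatrix).
# Returns n x H matrix, or (with cache=TRUE) a list with activations for
# the backward pass. ReLU on all layers except the linear output.
qnet_forward <- function(net, X, cache = FALSE) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  H <- X
  for (l in seq_len(L)) {
    Z <- as.matrix(H %*% net$W[[l]])
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    H <- if (l < L) pmax(Z, 0) else Z
    acts[[l + 1L]] <- H
  }
  if (cache) list(out = H, acts = acts) else H
}

# Backward pass from dOut = dLoss/dOutput (n x H). Returns gradients with
# the same shapes as net$W / net$b.
qnet_backward <- function(net, fwd, dOut) {
  L <- length(net$W)
  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- dOut
  for (l in rev(seq_len(L))) {
    A_prev <- fwd$acts[[l]]
    gW[[l]] <- as.matrix(Matrix::crossprod(A_prev, delta))
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$W[[l]])
      delta <- delta * (fwd$acts[[l]] > 0)   # ReLU mask of layer l-1 output
    }
  }
  list(W = gW, b = gb)
}

#' Huber loss
#'
#' The piecewise loss `x^2 / 2` for `|x| < 1` and `|x| - 1/2` otherwise;
#' continuous and once-differentiable at `|x| = 1`.
#'
#' @param x Numeric vector of residuals.
#' @return Elementwise Huber loss values.
#' @export
huber_loss <- function(x) {
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

huber_grad <- function(x) {
  ifelse(abs(x) < 1, x, sign(x))
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(net) {
  zeros <- function(p) if (is.matrix(p)) p * 0 else numeric(length(p))
  list(mW = lapply(net$W, zeros), vW = lapply(net$W, zeros),
       mb = lapply(net$b, zeros), vb = lapply(net$b, zeros),
       t = 0L)
}

# One Adam update with optional global-norm gradient clipping.
adam_update <- function(net, opt, grads, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, clip_norm = 10) {
  if (is.finite(clip_norm) && clip_norm > 0) {
    sq <- sum(vapply(grads$W, function(g) sum(g^2), numeric(1))) +
      sum(vapply(grads$b, function(g) sum(g^2), numeric(1)))
    gnorm <- sqrt(sq)
    if (gnorm > clip_norm) {
      scale <- clip_norm / gnorm
      grads$W <- lapply(grads$W, `*`, scale)
      grads$b <- lapply(grads$b, `*`, scale)
    }
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * grads$W[[l]]
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    net$W[[l]] <- net$W[[l]] - lr * (opt$mW[[l]] / bc1) /
      (sqrt(opt$vW[[l]] / bc2) + eps)
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * grads$b[[l]]
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    net$b[[l]] <- net$b[[l]] - lr * (opt$mb[[l]] / bc1) /
      (sqrt(opt$vb[[l]] / bc2) + eps)
  }
  list(net = net, opt = opt)
}

#' Q-values of candidate successor states
#'
#' Scores each candidate with the selected bootstrap head. The state value is
#' the maximum of this vector (`V(s) = max_a Q(s, a)`).
#'
#' @param net A [qnetwork()].
#' @param features Feature matrix (rows = candidates) or a single
#'   `state_features` object.
#' @param head Head index in `1:H`.
#' @return Numeric vector, one Q-value per candidate.
#' @export
q_values <- function(net, features, head = 1L) {
  if (inherits(features, "state_features"))
    features <- matrix(feature_vector(features), nrow = 1L)
  if (nrow(features) == 0L) stop("empty candidate list")
  stopifnot(head >= 1L, head <= net$heads)
  out <- qnet_forward(net, features)
  out[, head]
}

#' Piecewise-linear epsilon annealing schedule
#'
#' Exploration probability annealed from `start` at the first episode to
#' `end` at the last, linearly over the first `anneal_fraction` of episodes
#' and flat at `end` afterwards; monotone non-increasing.
#'
#' @param episode 0-based episode index (vectorized).
#' @param n_episodes Total number of training episodes.
#' @param start,end Endpoints of the schedule (defaults 1 and 0.01).
#' @param anneal_fraction Fraction of the run over which to anneal.
#' @return Numeric vector of epsilon values.
#' @export
epsilon_schedule <- function(episode, n_episodes, start = 1, end = 0.01,
                             anneal_fraction = 1) {
  if (n_episodes <= 1L) return(rep(end, length(episode)))
  span <- max(1, (n_episodes - 1) * anneal_fraction)
  frac <- pmin(1, episode / span)
  start + (end - start) * frac
}

#' Epsilon-greedy action selection over Q-values
#'
#' With probability `epsilon` a uniformly random candidate index, otherwise
#' the argmax of the Q-values with ties broken by the lowest index
#' (deterministic). Uses R's RNG stream.
#'
#' @param qvals Numeric vector of candidate Q-values.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return The chosen candidate index.
#' @export
select_action <- function(qvals, epsilon = 0) {
  n <- length(qvals)
  if (n == 0L) stop("empty action set")
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    sample.int(n, 1L)
  } else {
    which.max(qvals)   # first maximum = lowest-index tie-break
  }
}
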