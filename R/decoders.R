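#' Bank of per-type edge networks (the generative module)
#'
#' One small MLP per interaction type, all with identical architecture and
#' independent parameters, mapping the concatenated states of an edge's two
#' endpoints `[x_i, x_j]` to a d-vector. Two aggregation modes are
#' supported:
#'
#' * `"physics"`: the per-edge outputs are forces; a node's predicted state
#'   increment is their sum divided by its mass. Per-edge forces are then
#'   identifiable and can be checked against Newton's third law.
#' * `"mpnn"`: the per-edge outputs are messages; a separate node network
#'   maps the summed message together with the node's own state to the
#'   increment. Used when no physical constraints are available (e.g. time
#'   series).
#'
#' @param K number of interaction types.
#' @param state_dim length of one node's feature vector (for particles in d
#'   dimensions: position, velocity and mass, i.e. `2d + 1`).
#' @param out_dim dimension of the predicted increment.
#' @param hidden hidden-layer widths of every edge network.
#' @param activation hidden nonlinearity of all networks (see [mlp_new()]).
#' @param mode `"physics"` or `"mpnn"`.
#' @param msg_dim message width (`"mpnn"` mode only).
#' @param node_hidden hidden widths of the node network (`"mpnn"` only).
#' @param seed integer seed for the (independent) initializations.
#' @return an `edge_bank` object.
#' @export
edge_bank <- function(K, state_dim, out_dim, hidden = c(64, 64),
                      mode = c("physics", "mpnn"), msg_dim = 16L,
                      node_hidden = c(64), activation = "elu", seed = 1L) {
  mode <- match.arg(mode)
  edge_out <- if (mode == "physics") out_dim else msg_dim
  seeds <- .spawn_seeds(seed, K + 1L)
  nets <- lapply(seq_len(K), function(k) {
    mlp_new(c(2L * state_dim, hidden, edge_out), activation, seed = seeds[k])
  })
  node_net <- if (mode == "mpnn") {
    mlp_new(c(msg_dim + state_dim, node_hidden, out_dim), activation,
            seed = seeds[K + 1L])
  } else NULL
  structure(list(K = as.integer(K), state_dim = as.integer(state_dim),
                 out_dim = as.integer(out_dim), mode = mode,
                 msg_dim = if (mode == "mpnn") as.integer(msg_dim) else NULL,
                 nets = nets, node_net = node_net,
                 in_center = NULL, in_scale = NULL),
            class = "edge_bank")
}

# fixed affine input standardization, estimated once from training edge
# inputs; parameter-free, so gradients are unaffected
.bank_set_normalization <- function(bank, X) {
  bank$in_center <- colMeans(X)
  bank$in_scale <- pmax(apply(X, 2L, stats::sd), 1e-8)
  bank
}

.bank_input <- function(bank, X) {
  if (is.null(bank$in_center)) return(X)
  sweep(sweep(X, 2L, bank$in_center), 2L, bank$in_scale, "/")
}

# forward through one edge net with the bank's input normalization applied;
# the compiled kernel is used when no activation cache is required
.net_forward <- function(bank, k, X, cache = FALSE) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  Xn <- .bank_input(bank, X)
  if (!cache) return(.cpp_mlp_forward(bank$nets[[k]], Xn))
  mlp_forward(bank$nets[[k]], Xn, cache = TRUE)
}

#' Predict a node's state increment under a fixed subgraph realization
#'
#' Reference implementation of the generative module for one node at one
#' time step: each incoming edge contributes the output of the network
#' selected by the realization; physics mode sums the per-edge forces and
#' divides by the node's mass, message-passing mode feeds the summed message
#' and the node state through the node network.
#'
#' @param bank an [edge_bank()].
#' @param x_i state vector of the receiver node.
#' @param X_neigh matrix of neighbour states, one row per incoming edge (the
#'   node's neighbour slots, in slot order).
#' @param types integer vector assigning a type to every incoming edge
#'   (length must equal `nrow(X_neigh)`).
#' @param mass receiver mass (physics mode).
#' @return predicted increment (numeric vector of length `out_dim`).
#' @export
predict_increment_fixed <- function(bank, x_i, X_neigh, types, mass = NULL) {
  if (!is.matrix(X_neigh)) X_neigh <- matrix(X_neigh, nrow = 1L)
  if (length(types) != nrow(X_neigh)) {
    stop("realization assigns ", length(types), " types to ",
         nrow(X_neigh), " incoming edges")
  }
  stopifnot(all(types >= 1L), all(types <= bank$K))
  if (nrow(X_neigh) == 0L) {
    msg <- numeric(if (bank$mode == "physics") bank$out_dim else bank$msg_dim)
  } else {
    inp <- cbind(matrix(x_i, nrow(X_neigh), length(x_i), byrow = TRUE), X_neigh)
    msg <- 0
    for (k in unique(types)) {
      rows <- which(types == k)
      msg <- msg + colSums(.net_forward(bank, k, inp[rows, , drop = FALSE]))
    }
  }
  if (bank$mode == "physics") {
    if (is.null(mass)) stop("physics mode requires the receiver mass")
    msg / mass
  } else {
    as.numeric(mlp_forward(bank$node_net, c(msg, x_i)))
  }
}

#' Predict a node's increment over its currently active edges
#'
#' Same aggregation as [predict_increment_fixed()], restricted to the edges
#' active at the current time step of an evolving-topology system. An empty
#' active set yields a zero increment in physics mode.
#'
#' @inheritParams predict_increment_fixed
#' @param active logical or index vector selecting the active incoming
#'   edges among the rows of `X_neigh`; `types` must be given for active
#'   edges only.
#' @export
predict_increment_evolving <- function(bank, x_i, X_neigh, active, types,
                                       mass = NULL) {
  if (!is.matrix(X_neigh)) X_neigh <- matrix(X_neigh, nrow = 1L)
  act <- if (is.logical(active)) which(active) else as.integer(active)
  if (length(types) != length(act)) {
    stop("types supplied for ", length(types), " edges but ",
         length(act), " are active; supply types for active edges only")
  }
  predict_increment_fixed(bank, x_i, X_neigh[act, , drop = FALSE], types, mass)
}

#' Gaussian log-likelihood of an observed state increment
#'
#' `log N(obs | pred, sigma2 * I)`; the conditional likelihood of the
#' generative model, always handled in log space.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param sigma2 isotropic variance (> 0).
#' @return scalar log-density.
#' @export
log_likelihood_increment <- function(observed, predicted, sigma2) {
  stopifnot(length(observed) == length(predicted), sigma2 > 0)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("non-finite increment passed to the likelihood")
  }
  d <- length(observed)
  -0.5 * d * log(2 * pi * sigma2) - sum((observed - predicted)^2) / (2 * sigma2)
}

#' Evaluate one learned pairwise force
#'
#' Physics mode only: returns the type-`z` network's output for the ordered
#' pair (i receives, j acts). In message-passing mode per-edge forces are not
#' identifiable (messages are an arbitrary embedding) and an error is raised.
#'
#' @inheritParams predict_increment_fixed
#' @param z interaction type index.
#' @param x_j state vector of the acting node.
#' @return learned force on node i (numeric vector).
#' @export
pairwise_force_eval <- function(bank, z, x_i, x_j) {
  if (bank$mode != "physics") {
    stop("pairwise forces are only identifiable with the physics decoder; ",
         "the message-passing decoder learns an arbitrary edge embedding")
  }
  stopifnot(z >= 1L, z <= bank$K)
  as.numeric(.net_forward(bank, z, matrix(c(x_i, x_j), 1L)))
}

# flat parameter access across the whole bank (edge nets then node net)
.bank_flatten <- function(bank) {
  th <- lapply(bank$nets, mlp_flatten)
  if (!is.null(bank$node_net)) th <- c(th, list(mlp_flatten(bank$node_net)))
  th
}

.bank_unflatten <- function(bank, thetas) {
  for (k in seq_len(bank$K)) bank$nets[[k]] <- mlp_unflatten(bank$nets[[k]], thetas[[k]])
  if (!is.null(bank$node_net)) {
    bank$node_net <- mlp_unflatten(bank$node_net, thetas[[bank$K + 1L]])
  }
  bank
}
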