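#' Permutation-invariant edge-type accuracy
#'
#' Inferred type labels are only identified up to a relabeling, so accuracy
#' is maximized over all permutations of the `K` labels:
#' `max over alpha of mean(alpha(predicted) == truth)`. Exhaustive over the
#' `K!` permutations (practical for the small `K` of relational inference;
#' an error is raised beyond `K = 8`).
#'
#' @param predicted,true integer vectors of types over the same edge set.
#' @param K number of types.
#' @return list with `accuracy` and `alpha`, the best permutation as an
#'   integer vector (`alpha[p]` is the true-label space image of predicted
#'   label `p`).
#' @examples
#' permutation_accuracy(c(2, 2, 2, 1), c(1, 1, 2, 2), K = 2)$accuracy # 0.75
#' @export
permutation_accuracy <- function(predicted, true, K) {
  if (length(predicted) != length(true)) {
    stop("predicted and true types must cover the same edge set")
  }
  if (K > 8L) stop("exhaustive permutation search supports K <= 8")
  perms <- .all_perms(K)
  best <- -1
  best_a <- NULL
  for (r in seq_len(nrow(perms))) {
    a <- unname(perms[r, ])
    acc <- mean(a[predicted] == true)
    if (acc > best) { best <- acc; best_a <- a }
  }
  list(accuracy = best, alpha = best_a)
}

.all_perms <- function(K) {
  if (K == 1L) return(matrix(1L, 1L, 1L))
  sub <- .all_perms(K - 1L)
  out <- matrix(0L, 0L, K)
  for (pos in seq_len(K)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1L), drop = FALSE], K,
                            sub[, seq(pos, K - 1L)[seq_len(K - pos)],
                                drop = FALSE]))
  }
  out
}

# learned force evaluator: either an edge_bank in physics mode or a plain
# function(Xi, Xj, types) -> per-edge force matrix
.force_eval <- function(model) {
  if (is.function(model)) return(model)
  if (!inherits(model, "edge_bank")) stop("expected an edge_bank or function")
  if (model$mode != "physics") {
    stop("pairwise-force metrics require the physics decoder; ",
         "the message-passing decoder does not expose per-edge forces")
  }
  function(Xi, Xj, types) {
    out <- matrix(0, nrow(Xi), model$out_dim)
    for (k in unique(types)) {
      sel <- types == k
      out[sel, ] <- .net_forward(model, k,
                                 cbind(Xi[sel, , drop = FALSE],
                                       Xj[sel, , drop = FALSE]))
    }
    out
  }
}

# states of edge endpoints of one sim at a set of time steps, stacked
.edge_states <- function(traj, edges, steps) {
  S <- .node_states(traj)
  p <- dim(S)[3L]
  Xi <- do.call(rbind, lapply(steps, function(t) {
    matrix(S[t, edges[, 1L], ], nrow(edges), p)
  }))
  Xj <- do.call(rbind, lapply(steps, function(t) {
    matrix(S[t, edges[, 2L], ], nrow(edges), p)
  }))
  list(Xi = Xi, Xj = Xj)
}

#' Mean absolute error of the learned pairwise forces
#'
#' Compares the learned force of each edge against the ground-truth force
#' law, with the learned networks matched to the true types through the
#' accuracy permutation `alpha` (so the metric measures the quality of the
#' learned interaction functions, independent of type-classification
#' mistakes).
#'
#' @param model an [edge_bank()] (physics mode) or a function
#'   `(Xi, Xj, types) -> forces`.
#' @param alpha permutation from [permutation_accuracy()]; the network used
#'   for an edge of true type `z` is the one whose label maps to `z`.
#' @param data an `ri_dataset` with ground-truth typed graphs.
#' @param spec the `force_spec` that generated the data.
#' @param steps time steps to evaluate at (default: all stored steps).
#' @return scalar mean absolute error (componentwise).
#' @export
mae_ef <- function(model, alpha, data, spec, steps = NULL) {
  f <- .force_eval(model)
  inv <- order(alpha)          # inv[z]: predicted label mapped to true z
  errs <- 0; n <- 0
  for (sim in data) {
    traj <- sim$trajectory
    T_ <- dim(traj$positions)[1L]
    st <- if (is.null(steps)) seq_len(T_) else steps
    es <- .edge_states(traj, sim$graph$edges, st)
    types_rep <- rep(sim$graph$true_types, times = length(st))
    learned <- f(es$Xi, es$Xj, inv[types_rep])
    truth <- do.call(rbind, lapply(st, function(t) {
      .edge_forces(matrix(traj$positions[t, , ], dim(traj$positions)[2L]),
                   sim$graph$edges, sim$graph$true_types, spec,
                   extra = list(charges = traj$charges))
    }))
    errs <- errs + sum(abs(learned - truth))
    n <- n + length(truth)
  }
  errs / n
}

#' Newton's-third-law violation of the learned forces
#'
#' Mean componentwise absolute value of `f(i<-j) + f(j<-i)` over all edge
#' pairs present in both directions, at the requested time steps. Exactly
#' zero for any antisymmetric force law.
#'
#' @inheritParams mae_ef
#' @export
mae_symm <- function(model, alpha, data, steps = NULL) {
  f <- .force_eval(model)
  inv <- order(alpha)
  errs <- 0; n <- 0
  for (sim in data) {
    traj <- sim$trajectory
    edges <- sim$graph$edges
    key <- paste(edges[, 1L], edges[, 2L])
    rev_row <- match(paste(edges[, 2L], edges[, 1L]), key)
    keep <- which(!is.na(rev_row) & edges[, 1L] < edges[, 2L])
    if (!length(keep)) next
    T_ <- dim(traj$positions)[1L]
    st <- if (is.null(steps)) seq_len(T_) else steps
    es <- .edge_states(traj, edges, st)
    types_rep <- rep(sim$graph$true_types, times = length(st))
    fw <- f(es$Xi, es$Xj, inv[types_rep])
    E <- nrow(edges)
    for (b in seq_along(st) - 1L) {
      fwd <- fw[b * E + keep, , drop = FALSE]
      bwd <- fw[b * E + rev_row[keep], , drop = FALSE]
      errs <- errs + sum(abs(fwd + bwd))
      n <- n + length(fwd)
    }
  }
  errs / n
}

#' Rollout error of predicted states
#'
#' Rolls the learned model forward `horizon` steps from each simulation's
#' initial state with the same semi-implicit Euler integrator the simulators
#' use, holding the decoded edge types fixed, and reports the mean absolute
#' error of positions and velocities jointly at the final step.
#'
#' @param bank an [edge_bank()].
#' @param types decoded types per simulation (list aligned with `data`, as
#'   returned by [decode_edge_types()]).
#' @param data an `ri_dataset`.
#' @param horizon number of steps to roll (default 10).
#' @return scalar mean absolute error.
#' @export
mae_state <- function(bank, types, data, horizon = 10L) {
  errs <- 0; n <- 0
  for (s in seq_along(data)) {
    traj <- data[[s]]$trajectory
    if (inherits(traj, "series_trajectory")) {
      pred <- .rollout_series(bank, types[[s]], data[[s]], horizon)
      truth <- traj$values[1L + horizon, ]
      errs <- errs + sum(abs(pred - truth)); n <- n + length(truth)
    } else {
      ro <- .rollout_particles(bank, types[[s]], data[[s]], horizon)
      T_ <- 1L + horizon
      d <- dim(traj$positions)[3L]
      N <- dim(traj$positions)[2L]
      truth <- cbind(matrix(traj$positions[T_, , ], N, d),
                     matrix(traj$velocities[T_, , ], N, d))
      pred <- cbind(ro$pos, ro$vel)
      if (any(!is.finite(pred))) stop("rollout blew up before the horizon")
      errs <- errs + sum(abs(pred - truth)); n <- n + length(truth)
    }
  }
  errs / n
}

.rollout_particles <- function(bank, types, sim, horizon) {
  traj <- sim$trajectory
  edges <- sim$graph$edges
  N <- dim(traj$positions)[2L]
  d <- dim(traj$positions)[3L]
  pos <- matrix(traj$positions[1L, , ], N, d)
  vel <- matrix(traj$velocities[1L, , ], N, d)
  m <- traj$masses
  for (h in seq_len(horizon)) {
    Xi <- cbind(pos[edges[, 1L], , drop = FALSE],
                vel[edges[, 1L], , drop = FALSE], m[edges[, 1L]])
    Xj <- cbind(pos[edges[, 2L], , drop = FALSE],
                vel[edges[, 2L], , drop = FALSE], m[edges[, 2L]])
    if (bank$mode == "physics") {
      fe <- matrix(0, nrow(edges), d)
      for (k in unique(types)) {
        sel <- types == k
        fe[sel, ] <- .net_forward(bank, k, cbind(Xi[sel, , drop = FALSE],
                                                 Xj[sel, , drop = FALSE]))
      }
      a <- matrix(0, N, d)
      for (col in seq_len(d)) {
        sums <- rowsum(fe[, col], edges[, 1L])
        a[as.integer(rownames(sums)), col] <- sums
      }
      a <- a / m
    } else {
      msg <- matrix(0, nrow(edges), bank$msg_dim)
      for (k in unique(types)) {
        sel <- types == k
        msg[sel, ] <- .net_forward(bank, k, cbind(Xi[sel, , drop = FALSE],
                                                  Xj[sel, , drop = FALSE]))
      }
      agg <- matrix(0, N, bank$msg_dim)
      for (col in seq_len(bank$msg_dim)) {
        sums <- rowsum(msg[, col], edges[, 1L])
        agg[as.integer(rownames(sums)), col] <- sums
      }
      a <- mlp_forward(bank$node_net, cbind(agg, pos, vel, m))
    }
    vel <- vel + a * traj$dt
    pos <- pos + vel * traj$dt
  }
  list(pos = pos, vel = vel)
}

.rollout_series <- function(bank, types, sim, horizon) {
  traj <- sim$trajectory
  edges <- sim$graph$edges
  x <- traj$values[1L, ]
  for (h in seq_len(horizon)) {
    Xi <- matrix(x[edges[, 1L]], ncol = 1L)
    Xj <- matrix(x[edges[, 2L]], ncol = 1L)
    msg <- matrix(0, nrow(edges), bank$msg_dim)
    for (k in unique(types)) {
      sel <- types == k
      msg[sel, ] <- .net_forward(bank, k, cbind(Xi[sel, , drop = FALSE],
                                                Xj[sel, , drop = FALSE]))
    }
    agg <- matrix(0, length(x), bank$msg_dim)
    for (col in seq_len(bank$msg_dim)) {
      sums <- rowsum(msg[, col], edges[, 1L])
      agg[as.integer(rownames(sums)), col] <- sums
    }
    x <- x + as.numeric(mlp_forward(bank$node_net, cbind(agg, x)))
  }
  x
}

#' One-step acceleration error on an evolving-topology system
#'
#' Mean absolute error between the model's one-step predicted increments and
#' the ground-truth increments over the requested (test) time steps; the
#' headline supervised metric for systems whose interaction graph changes
#' every step, where a fixed-graph rollout is not defined.
#'
#' @param bank an [edge_bank()] (physics mode).
#' @param edge_types named integer vector of decoded types keyed by
#'   `"i,j"` directed pairs (see [decode_edge_types_evolving()]).
#' @param traj an `evolving_trajectory`.
#' @param steps time-step indices to evaluate (default all `1..T-1`).
#' @return scalar mean absolute error.
#' @export
mae_acceleration <- function(bank, edge_types, traj, steps = NULL) {
  T_ <- dim(traj$positions)[1L]
  if (is.null(steps)) steps <- seq_len(T_ - 1L)
  N <- dim(traj$positions)[2L]
  d <- dim(traj$positions)[3L]
  errs <- 0; n <- 0
  for (t in steps) {
    edges <- traj$neighbors[[t]]
    key <- paste0(edges[, 1L], ",", edges[, 2L])
    types <- unname(edge_types[key])
    if (any(is.na(types))) stop("missing decoded type for an active edge")
    pos <- matrix(traj$positions[t, , ], N, d)
    vel <- matrix(traj$velocities[t, , ], N, d)
    m <- traj$masses
    Xi <- cbind(pos[edges[, 1L], , drop = FALSE],
                vel[edges[, 1L], , drop = FALSE], m[edges[, 1L]])
    Xj <- cbind(pos[edges[, 2L], , drop = FALSE],
                vel[edges[, 2L], , drop = FALSE], m[edges[, 2L]])
    fe <- matrix(0, nrow(edges), d)
    for (k in unique(types)) {
      sel <- types == k
      fe[sel, ] <- .net_forward(bank, k, cbind(Xi[sel, , drop = FALSE],
                                               Xj[sel, , drop = FALSE]))
    }
    a <- matrix(0, N, d)
    for (col in seq_len(d)) {
      sums <- rowsum(fe[, col], edges[, 1L])
      a[as.integer(rownames(sums)), col] <- sums
    }
    a <- a / m
    errs <- errs + sum(abs(a - matrix(traj$increments[t, , ], N, d)))
    n <- n + N * d
  }
  errs / n
}
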