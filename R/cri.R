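#' Collective relational inference for fixed-topology systems
#'
#' The inference procedure treats each node's incoming-edge subgraph as one
#' collective latent variable over the `K^degree` joint type assignments,
#' computes its exact posterior by enumeration (E step), and alternates with
#' an analytic update of the realization prior plus a gradient step on the
#' per-type edge networks (M step). See `vignette("collective-inference")`.
#'
#' @name cri
NULL

# ---- internal vectorized representation ------------------------------------

.node_states <- function(traj) {
  if (inherits(traj, "particle_trajectory")) {
    dm <- dim(traj$positions)
    T_ <- dm[1L]; N <- dm[2L]; d <- dm[3L]
    S <- array(0, c(T_, N, 2L * d + 1L))
    S[, , seq_len(d)] <- traj$positions
    S[, , d + seq_len(d)] <- traj$velocities
    S[, , 2L * d + 1L] <- rep(traj$masses, each = T_)
    S
  } else if (inherits(traj, "series_trajectory")) {
    v <- traj$values
    array(v, c(nrow(v), ncol(v), 1L))
  } else stop("unsupported trajectory class")
}

.traj_targets <- function(traj) {
  if (inherits(traj, "particle_trajectory")) {
    traj$increments
  } else {
    inc <- traj$increments
    array(inc, c(nrow(inc), ncol(inc), 1L))
  }
}

.traj_masses <- function(traj) {
  if (inherits(traj, "particle_trajectory")) traj$masses else NULL
}

# Flatten a dataset into per-degree-group arrays. Within a group, rows are
# (node-sim)-major with time fastest; edge inputs are stored slot-major so
# slot j of every row occupies one contiguous block.
.build_arrays <- function(data) {
  stopifnot(inherits(data, "ri_dataset") || is.list(data))
  sims <- data
  per_sim <- lapply(sims, function(s) {
    S <- .node_states(s$trajectory)
    list(S = S, tgt = .traj_targets(s$trajectory),
         m = .traj_masses(s$trajectory), graph = s$graph)
  })
  p <- dim(per_sim[[1L]]$S)[3L]
  d <- dim(per_sim[[1L]]$tgt)[3L]
  Tn <- dim(per_sim[[1L]]$tgt)[1L]
  for (ps in per_sim) {
    if (dim(ps$tgt)[1L] != Tn) stop("all simulations must share T")
  }
  # enumerate node-sims grouped by in-degree
  ns_tab <- do.call(rbind, lapply(seq_along(per_sim), function(s) {
    g <- per_sim[[s]]$graph
    cbind(sim = s, node = seq_len(g$n_nodes),
          degree = lengths(g$neighbors))
  }))
  ns_tab <- ns_tab[ns_tab[, "degree"] > 0L, , drop = FALSE]
  groups <- list()
  for (g in sort(unique(ns_tab[, "degree"]))) {
    sel <- ns_tab[ns_tab[, "degree"] == g, , drop = FALSE]
    ns <- nrow(sel)
    nrows <- ns * Tn
    target <- matrix(0, nrows, d)
    mass <- rep(1, nrows)
    xi <- matrix(0, nrows, p)
    EdgeX <- matrix(0, g * nrows, 2L * p)
    edge_id <- matrix(0L, ns, g)     # (node-sim, slot) -> row in graph$edges
    for (a in seq_len(ns)) {
      s <- sel[a, "sim"]; i <- sel[a, "node"]
      ps <- per_sim[[s]]
      rows <- (a - 1L) * Tn + seq_len(Tn)
      target[rows, ] <- ps$tgt[, i, ]
      if (!is.null(ps$m)) mass[rows] <- ps$m[i]
      Si <- matrix(ps$S[seq_len(Tn), i, ], Tn, p)
      xi[rows, ] <- Si
      nb <- ps$graph$neighbors[[i]]
      first <- which(ps$graph$edges[, 1L] == i)[1L]
      for (j in seq_len(g)) {
        Sj <- matrix(ps$S[seq_len(Tn), nb[j], ], Tn, p)
        EdgeX[(j - 1L) * nrows + rows, ] <- cbind(Si, Sj)
        edge_id[a, j] <- first + j - 1L
      }
    }
    groups[[as.character(g)]] <- list(
      degree = g, ns = ns, Tn = Tn, d = d, p = p,
      target = target, mass = mass, xi = xi, EdgeX = EdgeX,
      edge_id = edge_id, sims = sel[, "sim"], nodes = sel[, "node"])
  }
  list(groups = groups, p = p, d = d, Tn = Tn, n_sims = length(sims))
}

# per-type edge messages, sliced per slot: msgs[[j]][[k]] is nrows x out
.edge_msgs <- function(bank, grp) {
  nrows <- grp$ns * grp$Tn
  lapply(seq_len(grp$degree), function(j) {
    block <- (j - 1L) * nrows + seq_len(nrows)
    lapply(seq_len(bank$K), function(k) {
      .net_forward(bank, k, grp$EdgeX[block, , drop = FALSE])
    })
  })
}

# predicted increment for one realization from sliced messages
.realization_pred <- function(bank, grp, msgs, assignment) {
  s <- 0
  for (j in seq_along(assignment)) s <- s + msgs[[j]][[assignment[j]]]
  if (bank$mode == "physics") {
    s / grp$mass
  } else {
    mlp_forward(bank$node_net, cbind(s, grp$xi))
  }
}

# log-likelihood matrix L[ns, z]: sum over t of log N(target | pred_z, s2 I)
.group_loglik <- function(bank, grp, msgs, tab, sigma2) {
  nz <- nrow(tab$phi)
  L <- matrix(0, grp$ns, nz)
  const <- -0.5 * grp$d * log(2 * pi * sigma2) * grp$Tn
  for (z in seq_len(nz)) {
    R <- .realization_pred(bank, grp, msgs, tab$phi[z, ]) - grp$target
    sq <- rowSums(R * R)
    L[, z] <- const - colSums(matrix(sq, grp$Tn, grp$ns)) / (2 * sigma2)
  }
  if (any(!is.finite(L))) {
    bad <- which(!is.finite(L), arr.ind = TRUE)[1L, ]
    stop("non-finite log-likelihood for node-sim ", bad[1L],
         " (degree ", grp$degree, "), realization ", bad[2L])
  }
  L
}

# ---- exported E-step / likelihood / Q --------------------------------------

#' Exact subgraph posteriors (E step)
#'
#' For every node of every simulation, the categorical posterior over the
#' joint type assignments of its incoming edges:
#' posterior(z) proportional to `pi_z * prod_t l(theta | target_t, z)`,
#' computed with summed log-likelihoods and log-sum-exp normalization.
#'
#' @param data an `ri_dataset` (list of `list(trajectory, graph)`).
#' @param bank an [edge_bank()] holding the current parameters.
#' @param priors a `realization_prior` (see [uniform_prior()]).
#' @param sigma2 Gaussian likelihood variance.
#' @return a `subgraph_posterior`: per simulation, a list of per-node
#'   probability vectors over that node's realization table.
#' @export
compute_posteriors <- function(data, bank, priors, sigma2) {
  arrays <- .build_arrays(data)
  post <- .posterior_matrices(arrays, bank, priors, sigma2)
  .package_posteriors(arrays, post, data, K = bank$K)
}

.posterior_matrices <- function(arrays, bank, priors, sigma2) {
  lapply(arrays$groups, function(grp) {
    tab <- enumerate_realizations(bank$K, grp$degree)
    msgs <- .edge_msgs(bank, grp)
    L <- .group_loglik(bank, grp, msgs, tab, sigma2)
    lp <- sweep(L, 2L, log(priors$tables[[as.character(grp$degree)]]), "+")
    post <- exp(lp - .logsumexp_rows(lp))
    post / rowSums(post)
  })
}

.package_posteriors <- function(arrays, post, data, K = NULL) {
  out <- lapply(seq_len(arrays$n_sims), function(s) {
    vector("list", data[[s]]$graph$n_nodes)
  })
  node_deg <- lapply(seq_len(arrays$n_sims), function(s) {
    integer(data[[s]]$graph$n_nodes)
  })
  for (gname in names(arrays$groups)) {
    grp <- arrays$groups[[gname]]
    P <- post[[gname]]
    for (a in seq_len(grp$ns)) {
      out[[grp$sims[a]]][[grp$nodes[a]]] <- P[a, ]
      node_deg[[grp$sims[a]]][grp$nodes[a]] <- grp$degree
    }
  }
  structure(out, class = "subgraph_posterior",
            node_degrees = node_deg, K = K)
}

#' Marginal log-likelihood of the observed increments
#'
#' `sum_i log sum_z pi_z exp(sum_t log l)`, the quantity the EM procedure
#' ascends; evaluated with log-sum-exp.
#'
#' @inheritParams compute_posteriors
#' @return scalar.
#' @export
marginal_log_likelihood <- function(data, bank, priors, sigma2) {
  arrays <- .build_arrays(data)
  .marginal_ll(arrays, bank, priors, sigma2)
}

.marginal_ll <- function(arrays, bank, priors, sigma2) {
  tot <- 0
  for (grp in arrays$groups) {
    tab <- enumerate_realizations(bank$K, grp$degree)
    msgs <- .edge_msgs(bank, grp)
    L <- .group_loglik(bank, grp, msgs, tab, sigma2)
    lp <- sweep(L, 2L, log(priors$tables[[as.character(grp$degree)]]), "+")
    tot <- tot + sum(.logsumexp_rows(lp))
  }
  tot
}

#' Expected complete-data log-likelihood (the Q function)
#'
#' `sum_i E_z[log pi_z] + sum_i E_z[sum_t log l]` under the supplied
#' posteriors.
#'
#' @param posteriors a `subgraph_posterior` from [compute_posteriors()].
#' @inheritParams compute_posteriors
#' @return scalar.
#' @export
q_value <- function(posteriors, priors, bank, data, sigma2) {
  arrays <- .build_arrays(data)
  post <- .posterior_from_packaged(arrays, posteriors)
  .q_full(arrays, post, bank, priors, sigma2)
}

.posterior_from_packaged <- function(arrays, posteriors) {
  lapply(arrays$groups, function(grp) {
    t(vapply(seq_len(grp$ns), function(a) {
      posteriors[[grp$sims[a]]][[grp$nodes[a]]]
    }, numeric(grp$K_pow %||% length(posteriors[[grp$sims[1L]]][[grp$nodes[1L]]]))))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.q_full <- function(arrays, post, bank, priors, sigma2) {
  tot <- 0
  for (gname in names(arrays$groups)) {
    grp <- arrays$groups[[gname]]
    P <- post[[gname]]
    tab <- enumerate_realizations(bank$K, grp$degree)
    msgs <- .edge_msgs(bank, grp)
    L <- .group_loglik(bank, grp, msgs, tab, sigma2)
    lpi <- log(priors$tables[[gname]])
    tot <- tot + sum(P %*% lpi) + sum(P * L)
  }
  tot
}

#' Analytic prior update (M step, prior part)
#'
#' The realization prior maximizing the expected log-prior term is the
#' average posterior; it is floored at `eps` and renormalized so that later
#' logarithms stay finite.
#'
#' @param posteriors a `subgraph_posterior`.
#' @param eps probability floor.
#' @return a `realization_prior`.
#' @export
update_priors <- function(posteriors, eps = 1e-8) {
  node_deg <- attr(posteriors, "node_degrees")
  rows <- list()
  degs <- integer(0L)
  for (s in seq_along(posteriors)) {
    for (i in seq_along(posteriors[[s]])) {
      pv <- posteriors[[s]][[i]]
      if (is.null(pv)) next
      rows[[length(rows) + 1L]] <- pv
      degs <- c(degs, node_deg[[s]][i])
    }
  }
  tabs <- lapply(sort(unique(degs)), function(g) {
    sel <- degs == g
    .floor_probs(Reduce(`+`, rows[sel]) / sum(sel), eps)
  })
  names(tabs) <- as.character(sort(unique(degs)))
  structure(list(K = attr(posteriors, "K"), tables = tabs),
            class = "realization_prior")
}

# ---- gradient of the Q data term -------------------------------------------

# Negative second Q term and its parameter gradients over the selected rows
# of one group (sum convention). rows indexes node-time pairs within grp.
.q_grad_group <- function(bank, grp, post, sigma2, rows) {
  g <- grp$degree
  nrows_all <- grp$ns * grp$Tn
  nb <- length(rows)
  tab <- enumerate_realizations(bank$K, g)
  nz <- nrow(tab$phi)
  er <- as.integer(outer(rows, (seq_len(g) - 1L) * nrows_all, `+`))
  EdgeB <- grp$EdgeX[er, , drop = FALSE]
  outs <- lapply(seq_len(bank$K), function(k) {
    .net_forward(bank, k, EdgeB, cache = TRUE)
  })
  block <- function(j) (j - 1L) * nb + seq_len(nb)
  msgs <- lapply(seq_len(g), function(j) {
    lapply(outs, function(o) o[block(j), , drop = FALSE])
  })
  tgt <- grp$target[rows, , drop = FALSE]
  mass <- grp$mass[rows]
  ns_of_row <- ((rows - 1L) %/% grp$Tn) + 1L
  dY <- lapply(seq_len(bank$K), function(k) matrix(0, g * nb, ncol(outs[[1L]])))
  node_grad <- NULL
  node_cachef <- NULL
  loss <- 0
  for (z in seq_len(nz)) {
    w <- post[ns_of_row, z]
    if (bank$mode == "physics") {
      s <- 0
      for (j in seq_len(g)) s <- s + msgs[[j]][[tab$phi[z, j]]]
      R <- s / mass - tgt
      loss <- loss + sum(w * rowSums(R * R)) / (2 * sigma2)
      wR <- (w / (sigma2 * mass)) * R
      for (j in seq_len(g)) {
        k <- tab$phi[z, j]
        dY[[k]][block(j), ] <- dY[[k]][block(j), ] + wR
      }
    } else {
      s <- 0
      for (j in seq_len(g)) s <- s + msgs[[j]][[tab$phi[z, j]]]
      inp <- cbind(s, grp$xi[rows, , drop = FALSE])
      out_n <- mlp_forward(bank$node_net, inp, cache = TRUE)
      R <- out_n - tgt
      loss <- loss + sum(w * rowSums(R * R)) / (2 * sigma2)
      gnode <- mlp_backward(bank$node_net, out_n, (w / sigma2) * R)
      node_grad <- if (is.null(node_grad)) gnode else
        list(W = Map(`+`, node_grad$W, gnode$W),
             b = Map(`+`, node_grad$b, gnode$b))
      dS <- gnode$dX[, seq_len(bank$msg_dim), drop = FALSE]
      for (j in seq_len(g)) {
        k <- tab$phi[z, j]
        dY[[k]][block(j), ] <- dY[[k]][block(j), ] + dS
      }
    }
  }
  grads <- lapply(seq_len(bank$K), function(k) {
    mlp_backward(bank$nets[[k]], outs[[k]], dY[[k]])
  })
  list(loss = loss, grads = grads, node_grad = node_grad)
}

#' One gradient step on the edge networks (M step, network part)
#'
#' Performs exactly one optimizer step on the negative expected data term of
#' the Q function, holding the posteriors fixed. With `line_search = TRUE`
#' the update is a plain gradient step whose length is halved until the Q
#' term does not decrease (the safeguard under which generalized-EM
#' monotonicity holds); otherwise a single Adam step is taken.
#'
#' @param posteriors a `subgraph_posterior` (current E step).
#' @inheritParams compute_posteriors
#' @param opt_state optimizer state from a previous call (or `NULL`).
#' @param lr learning rate / initial step length.
#' @param line_search halve the step until Q does not decrease.
#' @return list with the updated `bank`, `opt_state`, and `q_term` (the
#'   data term of Q after the step).
#' @export
m_step_theta <- function(posteriors, bank, data, sigma2, opt_state = NULL,
                         lr = 1e-3, line_search = FALSE) {
  arrays <- .build_arrays(data)
  post <- .posterior_from_packaged(arrays, posteriors)
  res <- .m_step(arrays, post, bank, sigma2, opt_state, lr, line_search,
                 minibatch = Inf, sweep_seed = NULL)
  res
}

# shared M-step engine: one full-batch step (minibatch = Inf) or a sweep of
# Adam minibatch steps over a seeded shuffle of the node-time rows
.m_step <- function(arrays, post, bank, sigma2, opt_state, lr, line_search,
                    minibatch, sweep_seed) {
  K <- bank$K
  n_nets <- K + as.integer(!is.null(bank$node_net))
  if (is.null(opt_state)) {
    opt_state <- lapply(seq_len(n_nets), function(i) {
      np <- length(mlp_flatten(if (i <= K) bank$nets[[i]] else bank$node_net))
      adam_new(np)
    })
  }
  eval_lossgrad <- function(rowsets) {
    total <- NULL
    loss <- 0
    for (gname in names(arrays$groups)) {
      grp <- arrays$groups[[gname]]
      rows <- rowsets[[gname]]
      if (!length(rows)) next
      r <- .q_grad_group(bank, grp, post[[gname]], sigma2, rows)
      loss <- loss + r$loss
      flat <- lapply(seq_len(K), function(k) .grad_flatten(r$grads[[k]]))
      if (!is.null(r$node_grad)) flat <- c(flat, list(.grad_flatten(r$node_grad)))
      total <- if (is.null(total)) flat else Map(`+`, total, flat)
    }
    list(loss = loss, flat = total)
  }
  all_rows <- lapply(arrays$groups, function(grp) seq_len(grp$ns * grp$Tn))
  if (is.infinite(minibatch)) {
    lg <- eval_lossgrad(all_rows)
    if (line_search) {
      n_all <- sum(vapply(all_rows, length, numeric(1L)))
      theta0 <- .bank_flatten(bank)
      step <- lr
      q0 <- .data_term(arrays, post, bank, sigma2)
      for (it in seq_len(30L)) {
        cand <- bank
        for (i in seq_len(n_nets)) {
          th <- theta0[[i]] - step * lg$flat[[i]] / n_all
          if (i <= K) cand$nets[[i]] <- mlp_unflatten(cand$nets[[i]], th)
          else cand$node_net <- mlp_unflatten(cand$node_net, th)
        }
        qc <- .data_term(arrays, post, cand, sigma2)
        if (qc >= q0) { bank <- cand; q0 <- qc; break }
        step <- step / 2
      }
      return(list(bank = bank, opt_state = opt_state, q_term = q0))
    }
    theta0 <- .bank_flatten(bank)
    for (i in seq_len(n_nets)) {
      st <- adam_step(opt_state[[i]], theta0[[i]], lg$flat[[i]], lr = lr)
      opt_state[[i]] <- st$state
      if (i <= K) bank$nets[[i]] <- mlp_unflatten(bank$nets[[i]], st$theta)
      else bank$node_net <- mlp_unflatten(bank$node_net, st$theta)
    }
    return(list(bank = bank, opt_state = opt_state,
                q_term = .data_term(arrays, post, bank, sigma2)))
  }
  # minibatch sweep: one Adam step per batch of node-time rows
  shuffled <- if (is.null(sweep_seed)) {
    lapply(all_rows, sample)
  } else {
    withr::with_seed(sweep_seed, lapply(all_rows, sample))
  }
  n_batches <- max(vapply(shuffled, function(r) ceiling(length(r) / minibatch),
                          numeric(1L)))
  for (b in seq_len(n_batches)) {
    rowsets <- lapply(shuffled, function(r) {
      lo <- (b - 1L) * minibatch + 1L
      if (lo > length(r)) integer(0L) else r[lo:min(b * minibatch, length(r))]
    })
    nb <- sum(vapply(rowsets, length, numeric(1L)))
    if (!nb) next
    lg <- eval_lossgrad(rowsets)
    theta0 <- .bank_flatten(bank)
    for (i in seq_len(n_nets)) {
      st <- adam_step(opt_state[[i]], theta0[[i]], lg$flat[[i]] / nb, lr = lr)
      opt_state[[i]] <- st$state
      if (i <= K) bank$nets[[i]] <- mlp_unflatten(bank$nets[[i]], st$theta)
      else bank$node_net <- mlp_unflatten(bank$node_net, st$theta)
    }
  }
  list(bank = bank, opt_state = opt_state, q_term = NA_real_)
}

# expected data term of Q (no prior term), sum over all rows
.data_term <- function(arrays, post, bank, sigma2) {
  tot <- 0
  for (gname in names(arrays$groups)) {
    grp <- arrays$groups[[gname]]
    tab <- enumerate_realizations(bank$K, grp$degree)
    msgs <- .edge_msgs(bank, grp)
    L <- .group_loglik(bank, grp, msgs, tab, sigma2)
    tot <- tot + sum(post[[gname]] * L)
  }
  tot
}

# ---- decoding --------------------------------------------------------------

#' Decode per-edge types from subgraph posteriors
#'
#' Per node, the most probable realization is selected (ties resolved to the
#' lowest realization index) and the phi mapping assigns each incoming edge
#' its type.
#'
#' @param posteriors a `subgraph_posterior`.
#' @param data the dataset the posteriors were computed on.
#' @return list (per simulation) of integer type vectors aligned with the
#'   rows of each simulation's `graph$edges`.
#' @export
decode_edge_types <- function(posteriors, data) {
  K <- attr(posteriors, "K")
  lapply(seq_along(data), function(s) {
    graph <- data[[s]]$graph
    types <- integer(nrow(graph$edges))
    for (i in seq_len(graph$n_nodes)) {
      pv <- posteriors[[s]][[i]]
      if (is.null(pv)) next
      g <- length(graph$neighbors[[i]])
      Ki <- if (!is.null(K)) K else round(length(pv)^(1 / g))
      tab <- enumerate_realizations(Ki, g)
      best <- which.max(pv)        # which.max takes the lowest index on ties
      types[graph$edges[, 1L] == i] <- tab$phi[best, ]
    }
    types
  })
}
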