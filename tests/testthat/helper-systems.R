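# Small fixtures and independent oracles shared across the test files.

# hand-built two-node, one-edge dataset with a stub trajectory:
# node 1 receives from node 2; states are fixed so likelihoods are easy to
# compute by hand
tiny_dataset <- function(n_sims = 1L, n_nodes = 3L, K = 2L, T_ = 3L,
                         seed = 42L, d = 2L) {
  spec <- spring_spec(c(0.5, 2.0)[seq_len(K)], c(2.0, 1.0)[seq_len(K)])
  simulate_springs(n_sims, n_nodes = n_nodes, spec = spec, n_steps = T_,
                   seed = seed, d = d)
}

# an edge bank whose type-k network always returns the constant vector
# consts[[k]] (weights zeroed, bias set): exercises aggregation contracts
# without any training
stub_bank <- function(K, state_dim, out_dim, consts) {
  bank <- edge_bank(K, state_dim, out_dim, hidden = c(4), seed = 1L)
  for (k in seq_len(K)) {
    net <- bank$nets[[k]]
    for (l in seq_along(net$W)) net$W[[l]][] <- 0
    net$b[[length(net$b)]][] <- consts[[k]]
    bank$nets[[k]] <- net
  }
  bank
}

# brute-force posterior over subgraph realizations: explicit loops and raw
# probability products (safe only for tiny T), independent of the package's
# log-space vectorized path
brute_force_posteriors <- function(data, bank, priors, sigma2) {
  lapply(data, function(sim) {
    traj <- sim$trajectory
    graph <- sim$graph
    S <- relinf:::.node_states(traj)
    tgt <- traj$increments
    lapply(seq_len(graph$n_nodes), function(i) {
      nb <- graph$neighbors[[i]]
      g <- length(nb)
      if (g == 0L) return(NULL)
      tab <- enumerate_realizations(bank$K, g)
      pi_g <- priors$tables[[as.character(g)]]
      w <- numeric(nrow(tab$phi))
      for (z in seq_len(nrow(tab$phi))) {
        lik <- 1
        for (t in seq_len(dim(tgt)[1L])) {
          pred <- predict_increment_fixed(
            bank, S[t, i, ], S[t, nb, , drop = TRUE], tab$phi[z, ],
            mass = traj$masses[i])
          dens <- prod(stats::dnorm(tgt[t, i, ], pred, sqrt(sigma2)))
          lik <- lik * dens
        }
        w[z] <- pi_g[z] * lik
      }
      w / sum(w)
    })
  })
}

# central-difference gradient of a scalar function
num_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1L))
}

all_true_types <- function(data) {
  unlist(lapply(data, function(s) s$graph$true_types))
}

# supervised-oracle bank: each type's net regressed directly onto the true
# pairwise force law over states visited by an evolving trajectory; used to
# validate the sequential inference machinery independently of EM training
oracle_trained_bank <- function(traj, force_fun, hidden = c(32, 32),
                                n_state_steps = 50L, n_train_steps = 2000L) {
  bank <- edge_bank(2, 5, 2, hidden = hidden, seed = 3)
  T_ <- dim(traj$positions)[1]
  S_all <- NULL
  set.seed(2)
  for (t in sample(seq_len(T_ - 1), min(n_state_steps, T_ - 1))) {
    e <- traj$neighbors[[t]]
    S <- relinf:::.evolving_states(traj, t)
    S_all <- rbind(S_all, cbind(S[e[, 1], ], S[e[, 2], ]))
  }
  bank <- relinf:::.bank_set_normalization(bank, S_all)
  Xn <- relinf:::.bank_input(bank, S_all)
  for (k in 1:2) {
    Y <- t(vapply(seq_len(nrow(S_all)), function(r) {
      force_fun(S_all[r, 1:2], S_all[r, 6:7], k)
    }, numeric(2)))
    net <- bank$nets[[k]]
    opt <- adam_new(length(mlp_flatten(net)))
    set.seed(k)
    for (step in seq_len(n_train_steps)) {
      idx <- sample(nrow(Xn), min(512, nrow(Xn)))
      out <- mlp_forward(net, Xn[idx, ], cache = TRUE)
      g <- mlp_backward(net, out, (out - Y[idx, ]) / length(idx))
      st <- adam_step(opt, mlp_flatten(net), relinf:::.grad_flatten(g),
                      lr = 1e-2 / (1 + step / 1000))
      opt <- st$state
      net <- mlp_unflatten(net, st$theta)
    }
    bank$nets[[k]] <- net
  }
  bank
}
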