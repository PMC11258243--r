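# Fixed-topology collective EM: E step vs brute-force Bayes, likelihood and
# Q identities, prior updates, the M-step contract, and decoding.

test_that("E-step posteriors equal the brute-force Bayes oracle", {
  set.seed(21)
  for (rep in 1:3) {
    K <- sample(2:3, 1)
    n_nodes <- sample(3:4, 1)
    spec <- spring_spec(seq(0.5, 2.5, length.out = K),
                        seq(2.0, 1.0, length.out = K))
    data <- simulate_springs(2, n_nodes = n_nodes, spec = spec, n_steps = 3,
                             seed = 100 + rep)
    bank <- edge_bank(K, 5, 2, hidden = c(6), seed = rep)
    priors <- uniform_prior(K, n_nodes - 1L)
    # make the prior non-trivial so the test exercises it
    set.seed(rep)
    pt <- runif(K^(n_nodes - 1L)); pt <- pt / sum(pt)
    priors$tables[[1L]] <- pt
    # sigma2 large enough that the oracle's raw products cannot underflow
    post <- compute_posteriors(data, bank, priors, sigma2 = 0.5)
    oracle <- brute_force_posteriors(data, bank, priors, sigma2 = 0.5)
    for (s in seq_along(data)) {
      for (i in seq_along(oracle[[s]])) {
        expect_equal(post[[s]][[i]], oracle[[s]][[i]], tolerance = 1e-8)
      }
    }
  }
})

test_that("posterior rows are normalized and a flat model gives flat posteriors", {
  data <- tiny_dataset(2, n_nodes = 4, T_ = 4, seed = 3)
  # stub bank: both types return the same constant, so likelihoods are equal
  bank <- stub_bank(2, 5, 2, consts = list(c(0, 0), c(0, 0)))
  priors <- uniform_prior(2, 3L)
  post <- compute_posteriors(data, bank, priors, 0.1)
  for (s in seq_along(data)) {
    for (pv in post[[s]]) {
      expect_equal(sum(pv), 1, tolerance = 1e-8)
      expect_true(all(pv >= 0))
      expect_equal(pv, rep(1 / 8, 8), tolerance = 1e-12)
    }
  }
})

test_that("single-neighbour posterior follows the two-line Bayes computation", {
  # one receiver with one incoming edge, K = 2, uniform prior, per-type
  # total likelihoods in ratio 3:1 -> posterior (0.75, 0.25)
  g <- interaction_graph(2, rbind(c(1, 2)), true_types = 1L, K = 2L)
  pos <- array(0, c(2, 2, 2)); pos[, 2, 1] <- 1   # node 2 sits at x = 1
  vel <- array(0, c(2, 2, 2))
  traj <- particle_trajectory(pos, vel, masses = c(1, 1), dt = 1)
  data <- structure(list(list(trajectory = traj, graph = g)),
                    class = "ri_dataset")
  s2 <- 0.5
  # choose constants so exp(-c1^2/(2 s2)) / exp(-c2^2/(2 s2)) = 3
  c2 <- 1.5
  c1 <- sqrt(c2^2 - 2 * s2 * log(3))
  bank <- stub_bank(2, 5, 2, consts = list(c(c1, 0), c(c2, 0)))
  post <- compute_posteriors(data, bank, uniform_prior(2, 1L), s2)
  expect_equal(post[[1]][[1]], c(0.75, 0.25), tolerance = 1e-10)
})

test_that("marginal log-likelihood matches brute force and K = 1 reduction", {
  data <- tiny_dataset(2, n_nodes = 3, T_ = 3, seed = 8)
  bank <- edge_bank(2, 5, 2, hidden = c(6), seed = 2)
  priors <- uniform_prior(2, 2L)
  s2 <- 0.5   # large enough that raw products stay positive
  brute <- 0
  for (sim in data) {
    S <- relinf:::.node_states(sim$trajectory)
    tgt <- sim$trajectory$increments
    for (i in 1:3) {
      nb <- sim$graph$neighbors[[i]]
      tab <- enumerate_realizations(2, 2)
      tot <- 0
      for (z in 1:4) {
        lik <- 1
        for (t in 1:2) {
          pred <- predict_increment_fixed(bank, S[t, i, ], S[t, nb, ],
                                          tab$phi[z, ], sim$trajectory$masses[i])
          lik <- lik * prod(dnorm(tgt[t, i, ], pred, sqrt(s2)))
        }
        tot <- tot + 0.25 * lik
      }
      brute <- brute + log(tot)
    }
  }
  expect_equal(marginal_log_likelihood(data, bank, priors, s2), brute,
               tolerance = 1e-8)
  # K = 1: degenerate mixture reduces to the plain supervised log-likelihood
  b1 <- edge_bank(1, 5, 2, hidden = c(6), seed = 2)
  p1 <- uniform_prior(1, 2L)
  mll <- marginal_log_likelihood(data, b1, p1, s2)
  direct <- 0
  for (sim in data) {
    S <- relinf:::.node_states(sim$trajectory)
    tgt <- sim$trajectory$increments
    for (i in 1:3) {
      nb <- sim$graph$neighbors[[i]]
      for (t in 1:2) {
        pred <- predict_increment_fixed(b1, S[t, i, ], S[t, nb, ], c(1, 1),
                                        sim$trajectory$masses[i])
        direct <- direct + log_likelihood_increment(tgt[t, i, ], pred, s2)
      }
    }
  }
  expect_equal(mll, direct, tolerance = 1e-8)
})

test_that("Q, marginal likelihood and posterior entropy satisfy the EM identity", {
  data <- tiny_dataset(1, n_nodes = 3, T_ = 3, seed = 13)
  bank <- edge_bank(2, 5, 2, hidden = c(6), seed = 5)
  priors <- uniform_prior(2, 2L)
  post <- compute_posteriors(data, bank, priors, 0.05)
  q <- q_value(post, priors, bank, data, 0.05)
  mll <- marginal_log_likelihood(data, bank, priors, 0.05)
  entropy <- -sum(vapply(post[[1]], function(pv) sum(pv * log(pv)), numeric(1)))
  # log L = Q + H(posterior) at the E-step fixed point
  expect_equal(mll, q + entropy, tolerance = 1e-8)
  # point-mass posterior collapses Q to a single realization's terms
  pm <- post
  for (i in 1:3) {
    v <- rep(0, 4); v[2] <- 1
    pm[[1]][[i]] <- v
  }
  qpm <- q_value(pm, priors, bank, data, 0.05)
  manual <- 0
  S <- relinf:::.node_states(data[[1]]$trajectory)
  tgt <- data[[1]]$trajectory$increments
  tab <- enumerate_realizations(2, 2)
  for (i in 1:3) {
    manual <- manual + log(0.25)
    nb <- data[[1]]$graph$neighbors[[i]]
    for (t in 1:2) {
      pred <- predict_increment_fixed(bank, S[t, i, ], S[t, nb, ],
                                      tab$phi[2, ], data[[1]]$trajectory$masses[i])
      manual <- manual + log_likelihood_increment(tgt[t, i, ], pred, 0.05)
    }
  }
  expect_equal(qpm, manual, tolerance = 1e-8)
})

test_that("prior update averages posteriors, floors and renormalizes", {
  data <- tiny_dataset(1, n_nodes = 3, T_ = 3, seed = 2)
  bank <- edge_bank(2, 5, 2, hidden = c(4), seed = 1)
  post <- compute_posteriors(data, bank, uniform_prior(2, 2L), 0.1)
  # two point masses on different realizations average to (0.5, 0.5, 0, 0)
  post[[1]][[1]] <- c(1, 0, 0, 0)
  post[[1]][[2]] <- c(0, 1, 0, 0)
  post[[1]][[3]] <- c(0, 1, 0, 0)
  pr <- update_priors(post)
  expect_equal(sum(pr$tables[["2"]]), 1)
  expect_equal(pr$tables[["2"]], c(1, 2, 0, 0) / 3, tolerance = 1e-7)
  expect_true(all(pr$tables[["2"]] >= 1e-9))
  # identical posteriors: the prior equals them
  for (i in 1:3) post[[1]][[i]] <- c(0.4, 0.3, 0.2, 0.1)
  pr2 <- update_priors(post)
  expect_equal(pr2$tables[["2"]], c(0.4, 0.3, 0.2, 0.1), tolerance = 1e-7)
  # oracle: the analytic average maximizes the expected log-prior term
  # over the simplex (compare against random perturbations)
  obj <- function(p) sum(vapply(post[[1]], function(pv) sum(pv * log(p)),
                                numeric(1)))
  base <- obj(pr2$tables[["2"]])
  set.seed(3)
  for (r in 1:20) {
    cand <- pr2$tables[["2"]] + runif(4, -0.05, 0.05)
    cand <- pmax(cand, 1e-6); cand <- cand / sum(cand)
    expect_lte(obj(cand), base + 1e-10)
  }
})

test_that("one M step: zero learning rate is a no-op; gradient matches FD", {
  data <- tiny_dataset(1, n_nodes = 3, T_ = 3, seed = 31)
  bank <- edge_bank(2, 5, 2, hidden = c(5), seed = 7)
  priors <- uniform_prior(2, 2L)
  post <- compute_posteriors(data, bank, priors, 0.05)
  res0 <- m_step_theta(post, bank, data, 0.05, lr = 0)
  expect_equal(mlp_flatten(res0$bank$nets[[1]]), mlp_flatten(bank$nets[[1]]))
  # finite differences of the expected data term vs the internal gradient
  arrays <- relinf:::.build_arrays(data)
  pm <- relinf:::.posterior_from_packaged(arrays, post)
  grp <- arrays$groups[[1]]
  r <- relinf:::.q_grad_group(bank, grp, pm[[1]], 0.05,
                              seq_len(grp$ns * grp$Tn))
  for (k in 1:2) {
    f <- function(th) {
      b2 <- bank
      b2$nets[[k]] <- mlp_unflatten(b2$nets[[k]], th)
      relinf:::.q_grad_group(b2, grp, pm[[1]], 0.05,
                             seq_len(grp$ns * grp$Tn))$loss
    }
    ng <- num_grad(f, mlp_flatten(bank$nets[[k]]))
    expect_equal(relinf:::.grad_flatten(r$grads[[k]]), ng,
                 tolerance = 1e-4 * max(1, max(abs(ng))))
  }
})

test_that("with point-mass posteriors the M objective is the supervised loss", {
  data <- tiny_dataset(1, n_nodes = 3, T_ = 3, seed = 17)
  bank <- edge_bank(2, 5, 2, hidden = c(5), seed = 3)
  arrays <- relinf:::.build_arrays(data)
  grp <- arrays$groups[[1]]
  pm <- matrix(0, grp$ns, 4); pm[, 3] <- 1       # all nodes on realization 3
  r <- relinf:::.q_grad_group(bank, grp, pm, 0.05, seq_len(grp$ns * grp$Tn))
  tab <- enumerate_realizations(2, 2)
  S <- relinf:::.node_states(data[[1]]$trajectory)
  tgt <- data[[1]]$trajectory$increments
  manual <- 0
  for (i in 1:3) {
    nb <- data[[1]]$graph$neighbors[[i]]
    for (t in 1:2) {
      pred <- predict_increment_fixed(bank, S[t, i, ], S[t, nb, ], tab$phi[3, ],
                                      data[[1]]$trajectory$masses[i])
      manual <- manual + sum((tgt[t, i, ] - pred)^2) / (2 * 0.05)
    }
  }
  expect_equal(r$loss, manual, tolerance = 1e-10)
})

test_that("decoding picks the argmax realization and maps through phi", {
  data <- tiny_dataset(1, n_nodes = 3, T_ = 3, seed = 5)
  bank <- edge_bank(2, 5, 2, hidden = c(4), seed = 1)
  post <- compute_posteriors(data, bank, uniform_prior(2, 2L), 0.1)
  tab <- enumerate_realizations(2, 2)
  # point mass: edges typed exactly by phi of that realization
  post[[1]][[1]] <- c(0, 0, 1, 0)
  post[[1]][[2]] <- c(0, 1, 0, 0)
  post[[1]][[3]] <- rep(0.25, 4)   # uniform: tie broken to realization 1
  ty <- decode_edge_types(post, data)[[1]]
  e <- data[[1]]$graph$edges
  expect_equal(ty[e[, 1] == 1], tab$phi[3, ])
  expect_equal(ty[e[, 1] == 2], tab$phi[2, ])
  expect_equal(ty[e[, 1] == 3], tab$phi[1, ])
  # agreement with an exhaustive per-realization argmax on random posteriors
  set.seed(9)
  for (r in 1:10) {
    pv <- runif(4); pv <- pv / sum(pv)
    post[[1]][[2]] <- pv
    ty2 <- decode_edge_types(post, data)[[1]]
    expect_equal(ty2[e[, 1] == 2], tab$phi[which.max(pv), ])
  }
})

test_that("fitting is deterministic given the seed", {
  data <- tiny_dataset(3, n_nodes = 3, T_ = 5, seed = 41)
  cfg <- cri_config(epochs = 3, hidden = c(6), seed = 11, minibatch = 16)
  f1 <- fit_cri(data, K = 2, cfg)
  f2 <- fit_cri(data, K = 2, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$types, f2$types)
})

test_that("marginal log-likelihood is non-decreasing in line-search mode", {
  data <- tiny_dataset(2, n_nodes = 3, T_ = 6, seed = 23)
  cfg <- cri_config(epochs = 12, hidden = c(8), seed = 3, line_search = TRUE,
                    lr = 0.5)
  fit <- fit_cri(data, K = 2, cfg)
  expect_true(all(diff(fit$history$marginal_ll) > -1e-6))
})
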