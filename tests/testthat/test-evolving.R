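# Evolving-topology inference: sequential Bayes updates, exactness at the
# first step, the maximum-entropy limit, and the fit loop contracts.

# hand-built one-receiver system: node 1 receives from nodes 2..(1+g) at
# every step; states are constants so stub-bank likelihoods are easy to
# control through the target increments
toy_evolving <- function(g, T_, target = c(0, 0), masses = NULL) {
  N <- g + 1L
  pos <- array(0, c(T_, N, 2))
  for (j in seq_len(g)) pos[, 1 + j, 1] <- j       # distinct positions
  vel <- array(0, c(T_, N, 2))
  inc <- array(0, c(T_ - 1L, N, 2))
  inc[, 1, 1] <- target[1]; inc[, 1, 2] <- target[2]
  edges <- cbind(1L, 1L + seq_len(g))
  structure(list(positions = pos, velocities = vel,
                 masses = masses %||% rep(1, N), dt = 1, increments = inc,
                 neighbors = rep(list(edges), T_), kinds = NULL,
                 type_of = NULL, K = 2L),
            class = "evolving_trajectory")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("posteriors start at the prior as independent copies", {
  tr <- toy_evolving(3, 5)
  P <- init_edge_posteriors(tr, c(0.9, 0.1))
  expect_equal(nrow(P), 3L)
  expect_true(all(P[, 1] == 0.9))
  P[1, ] <- c(0.2, 0.8)
  expect_equal(P[2, ], c(0.9, 0.1))   # no aliasing between rows
  expect_error(init_edge_posteriors(tr, c(0.7, 0.1)), "sum")
})

test_that("a single active edge follows plain Bayes", {
  # stub forces (1,0) and (3,0); target chosen so the likelihood ratio
  # gives posterior (0.25, 0.75) from a uniform start
  s2 <- 2
  # solve exp(-(x-1)^2/(2 s2)) / exp(-(x-3)^2/(2 s2)) = 1/3
  x <- 2 + s2 * log(3) / 2
  tr <- toy_evolving(1, 3, target = c(x, 0))
  bank <- stub_bank(2, 5, 2, consts = list(c(1, 0), c(3, 0)))
  P <- init_edge_posteriors(tr, c(0.5, 0.5))
  P1 <- sequential_update(P, tr, 1, bank, s2)
  expect_equal(unname(P1[1, ]), c(0.25, 0.75), tolerance = 1e-10)
})

test_that("type-independent likelihoods leave posteriors unchanged", {
  tr <- toy_evolving(3, 4, target = c(0.7, -0.2))
  bank <- stub_bank(2, 5, 2, consts = list(c(1, 1), c(1, 1)))
  P <- init_edge_posteriors(tr, c(0.5, 0.5))
  P[1, ] <- c(0.3, 0.7); P[2, ] <- c(0.8, 0.2)
  P1 <- sequential_update(P, tr, 1, bank, 0.5)
  expect_equal(unclass(P1), unclass(P), tolerance = 1e-12)
})

test_that("first update equals the exact joint posterior's marginals", {
  # 3 active edges, uniform start: the factorized recursion is exact at t=1
  tr <- toy_evolving(3, 3, target = c(1.2, -0.4), masses = c(1.7, 1, 1, 1))
  bank <- edge_bank(2, 5, 2, hidden = c(6), seed = 4)  # arbitrary nets
  s2 <- 0.3
  P <- init_edge_posteriors(tr, c(0.5, 0.5))
  P1 <- sequential_update(P, tr, 1, bank, s2)
  # brute-force joint over 2^3 typings
  tab <- enumerate_realizations(2, 3)
  S <- relinf:::.evolving_states(tr, 1)
  w <- numeric(8)
  for (z in 1:8) {
    pred <- predict_increment_fixed(bank, S[1, ], S[2:4, ], tab$phi[z, ],
                                    mass = 1.7)
    w[z] <- prod(rep(0.5, 3)) *
      exp(log_likelihood_increment(c(1.2, -0.4), pred, s2))
  }
  w <- w / sum(w)
  for (j in 1:3) {
    marg <- c(sum(w[tab$phi[, j] == 1]), sum(w[tab$phi[, j] == 2]))
    expect_equal(unname(P1[paste0("1,", 1 + j), ]), marg, tolerance = 1e-8)
  }
})

test_that("updates stay normalized across a whole trajectory", {
  al <- simulate_alternating_springs(n_nodes = 5, n_steps = 30, seed = 6)
  bank <- edge_bank(2, 5, 2, hidden = c(8), seed = 2)
  P <- init_edge_posteriors(al, c(0.5, 0.5))
  for (t in 1:29) {
    P <- sequential_update(P, al, t, bank, 0.05)
    expect_true(all(abs(rowSums(P) - 1) < 1e-8))
    expect_true(all(P >= 0))
  }
})

test_that("edge ordering within a time step does not affect the update", {
  al <- simulate_alternating_springs(n_nodes = 5, n_steps = 10, seed = 9)
  bank <- edge_bank(2, 5, 2, hidden = c(8), seed = 3)
  P <- init_edge_posteriors(al, c(0.5, 0.5))
  al2 <- al
  set.seed(1)
  al2$neighbors <- lapply(al$neighbors, function(e) {
    e[sample(nrow(e)), , drop = FALSE]
  })
  P1 <- sequential_update(P, al, 3, bank, 0.05)
  P2 <- sequential_update(P, al2, 3, bank, 0.05)
  expect_equal(unclass(P1), unclass(P2), tolerance = 1e-12)
})

test_that("information monotonically favors the truth for a single edge", {
  # likelihood strictly favors type 1 at every step: posterior mass on
  # type 1 never decreases
  tr <- toy_evolving(1, 12, target = c(1, 0))
  bank <- stub_bank(2, 5, 2, consts = list(c(1, 0), c(2, 0)))
  P <- init_edge_posteriors(tr, c(0.5, 0.5))
  masses <- numeric(0)
  for (t in 1:11) {
    P <- sequential_update(P, tr, t, bank, 1)
    masses <- c(masses, P[1, 1])
  }
  expect_true(all(diff(masses) >= -1e-12))
  expect_gt(masses[11], 0.9)
})

test_that("tau update averages posteriors; Q matches enumeration on a toy", {
  P <- init_edge_posteriors(c("1,2", "1,3"), c(0.5, 0.5))
  P[1, ] <- c(1, 0); P[2, ] <- c(0, 1)
  expect_equal(update_tau(P), c(0.5, 0.5))
  P[2, ] <- c(1, 0)
  expect_equal(update_tau(P), c(1, 0) , tolerance = 1e-7)
  # shared posterior: tau equals it
  P[1, ] <- c(0.3, 0.7); P[2, ] <- c(0.3, 0.7)
  expect_equal(update_tau(P), c(0.3, 0.7), tolerance = 1e-7)
  # Q data term vs exhaustive enumeration over joint typings (2 edges)
  tr <- toy_evolving(2, 2, target = c(0.5, 0.1))
  bank <- edge_bank(2, 5, 2, hidden = c(5), seed = 8)
  P <- init_edge_posteriors(tr, c(0.5, 0.5))
  P[1, ] <- c(0.6, 0.4); P[2, ] <- c(0.2, 0.8)
  tau <- c(0.5, 0.5)
  q <- q_evolving(P, tau, bank, tr, 0.3, steps = 1)
  S <- relinf:::.evolving_states(tr, 1)
  tab <- enumerate_realizations(2, 2)
  manual <- sum(P %*% log(tau))
  for (z in 1:4) {
    w <- P[1, tab$phi[z, 1]] * P[2, tab$phi[z, 2]]
    pred <- predict_increment_fixed(bank, S[1, ], S[2:3, ], tab$phi[z, ],
                                    mass = 1)
    manual <- manual + w * log_likelihood_increment(c(0.5, 0.1), pred, 0.3)
  }
  expect_equal(q, manual, tolerance = 1e-10)
})

test_that("fitting with zero observations returns the uniform prior exactly", {
  al <- simulate_alternating_springs(n_nodes = 4, n_steps = 8, seed = 3)
  fit <- fit_evolving_cri(al, 3, cri_config(epochs = 2, hidden = c(4), seed = 1),
                          train_steps = integer(0))
  expect_identical(fit$tau, rep(1 / 3, 3))
  expect_true(all(fit$posteriors == 1 / 3))
})

test_that("evolving decode takes the per-edge argmax with low-index ties", {
  P <- init_edge_posteriors(c("1,2", "2,1", "3,1"), c(0.5, 0.5))
  P[1, ] <- c(0.1, 0.9)
  P[3, ] <- c(0.5, 0.5)
  ty <- decode_edge_types_evolving(P)
  expect_equal(unname(ty), c(2L, 1L, 1L))
  expect_equal(names(ty), c("1,2", "2,1", "3,1"))
})

test_that("evolving fit is deterministic given the seed", {
  al <- simulate_alternating_springs(n_nodes = 4, n_steps = 12, seed = 5)
  cfg <- cri_config(epochs = 2, hidden = c(5), seed = 7)
  f1 <- fit_evolving_cri(al, 2, cfg, train_steps = 1:8, val_steps = 9:11)
  f2 <- fit_evolving_cri(al, 2, cfg, train_steps = 1:8, val_steps = 9:11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$posteriors, f2$posteriors)
})

test_that("sequential inference recovers types given well-fit force networks", {
  # alternating-topology two-type spring system; the per-type networks are
  # regressed directly onto the true force laws, and the evolving posterior
  # recursion alone must then identify every edge's type
  al <- simulate_alternating_springs(n_nodes = 5, n_steps = 100, seed = 31)
  spec <- spring_spec()
  bank <- oracle_trained_bank(al, function(pi_, pj, k) {
    spring_force(pi_, pj, spec$k[k], spec$L[k])
  })
  P <- init_edge_posteriors(al, c(0.5, 0.5))
  for (t in 1:99) P <- sequential_update(P, al, t, bank, 0.01)
  ty <- decode_edge_types_evolving(P)
  truth <- vapply(strsplit(names(ty), ","), function(p) {
    al$type_of(as.integer(p[1]), as.integer(p[2]))
  }, integer(1))
  acc <- permutation_accuracy(unname(ty), truth, 2)$accuracy
  expect_gte(acc, 0.9)
})
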