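# Evaluation metrics: permutation accuracy against enumeration oracles,
# force-error metrics against hand values and brute-force loops.

test_that("permutation accuracy handles the worked case and invariances", {
  # truth (1,1,2,2) vs predicted (2,2,2,1): swap permutation gives 3/4
  r <- permutation_accuracy(c(2, 2, 2, 1), c(1, 1, 2, 2), K = 2)
  expect_equal(r$accuracy, 0.75)
  expect_equal(r$alpha, c(2L, 1L))
  # exact predictions and globally flipped labels both score 1
  expect_equal(permutation_accuracy(c(1, 2, 1), c(1, 2, 1), 2)$accuracy, 1)
  expect_equal(permutation_accuracy(c(2, 1, 2), c(1, 2, 1), 2)$accuracy, 1)
  expect_error(permutation_accuracy(c(1, 2), c(1, 2, 1), 2), "same edge set")
})

test_that("permutation accuracy matches a brute-force oracle on random cases", {
  # independent oracle: explicit loop over permutations generated by a
  # different mechanism (filtering the K^K label maps down to bijections)
  oracle <- function(pred, truth, K) {
    maps <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    maps <- maps[apply(maps, 1, function(m) length(unique(m)) == K), ,
                 drop = FALSE]
    max(apply(maps, 1, function(m) mean(m[pred] == truth)))
  }
  set.seed(14)
  for (r in 1:200) {
    K <- sample(2:4, 1)
    n <- sample(4:12, 1)
    pred <- sample.int(K, n, replace = TRUE)
    truth <- sample.int(K, n, replace = TRUE)
    got <- permutation_accuracy(pred, truth, K)
    expect_equal(got$accuracy, oracle(pred, truth, K))
    # relabeling the predictions never changes the score
    perm <- sample.int(K)
    expect_equal(permutation_accuracy(perm[pred], truth, K)$accuracy,
                 got$accuracy)
  }
  # a constant prediction scores exactly the majority-class frequency
  truth <- c(1, 1, 1, 2, 2, 3)
  expect_equal(permutation_accuracy(rep(2, 6), truth, 3)$accuracy, 0.5)
})

test_that("ground-truth forces give zero third-law violation", {
  spec <- spring_spec()
  data <- simulate_springs(2, seed = 3, n_steps = 10)
  true_f <- function(Xi, Xj, types) {
    t(vapply(seq_len(nrow(Xi)), function(r) {
      spring_force(Xi[r, 1:2], Xj[r, 1:2], spec$k[types[r]], spec$L[types[r]])
    }, numeric(2)))
  }
  expect_equal(mae_symm(true_f, c(1, 2), data, steps = c(1, 5)), 0,
               tolerance = 1e-14)
  # and zero pairwise-force error, by definition
  expect_equal(mae_ef(true_f, c(1, 2), data, spec, steps = c(1, 5)), 0,
               tolerance = 1e-14)
})

test_that("constant-force models give the predicted metric values", {
  data <- simulate_springs(1, seed = 8, n_steps = 5)
  cvec <- c(0.4, -0.2)
  const_f <- function(Xi, Xj, types) {
    matrix(cvec, nrow(Xi), 2, byrow = TRUE)
  }
  # |f(i<-j) + f(j<-i)| = |2c| for every pair and component
  expect_equal(mae_symm(const_f, c(1, 2), data, steps = 1),
               mean(abs(2 * cvec)), tolerance = 1e-12)
  # mae_ef of (truth + offset) is the mean absolute offset
  spec <- spring_spec()
  offset_f <- function(Xi, Xj, types) {
    t(vapply(seq_len(nrow(Xi)), function(r) {
      spring_force(Xi[r, 1:2], Xj[r, 1:2], spec$k[types[r]], spec$L[types[r]]) +
        cvec
    }, numeric(2)))
  }
  expect_equal(mae_ef(offset_f, c(1, 2), data, spec, steps = c(1, 3)),
               mean(abs(cvec)), tolerance = 1e-12)
})

test_that("mae_symm agrees with a brute-force double loop over edge pairs", {
  data <- simulate_springs(1, seed = 5, n_steps = 4)
  bank <- edge_bank(2, 5, 2, hidden = c(6), seed = 2)
  got <- mae_symm(bank, c(1, 2), data, steps = c(2, 4))
  sim <- data[[1]]
  S <- relinf:::.node_states(sim$trajectory)
  e <- sim$graph$edges
  tot <- 0; n <- 0
  for (t in c(2, 4)) {
    for (r in seq_len(nrow(e))) {
      i <- e[r, 1]; j <- e[r, 2]
      if (i >= j) next
      z <- sim$graph$true_types[r]
      fij <- pairwise_force_eval(bank, z, S[t, i, ], S[t, j, ])
      zr <- sim$graph$true_types[e[, 1] == j & e[, 2] == i]
      fji <- pairwise_force_eval(bank, zr, S[t, j, ], S[t, i, ])
      tot <- tot + sum(abs(fij + fji)); n <- n + 2
    }
  }
  expect_equal(got, tot / n, tolerance = 1e-12)
})

test_that("rollout state error is zero for static systems and small for truth", {
  # zero-force decoder on a static system: nothing moves, error 0
  spec0 <- spring_spec(c(0, 0), c(1, 1))
  g <- full_graph(3, 2, seed = 1)
  pos <- array(rnorm(3 * 2), c(1, 3, 2))[rep(1, 20), , , drop = FALSE]
  vel <- array(0, c(20, 3, 2))
  traj <- particle_trajectory(pos, vel, masses = rep(1, 3), dt = 0.01)
  data <- structure(list(list(trajectory = traj, graph = g)),
                    class = "ri_dataset")
  zero_bank <- stub_bank(2, 5, 2, consts = list(c(0, 0), c(0, 0)))
  expect_equal(mae_state(zero_bank, list(g$true_types), data, horizon = 10), 0)
  # metrics are pure: repeated evaluation is identical
  data2 <- simulate_springs(1, seed = 2)
  bank <- edge_bank(2, 5, 2, hidden = c(6), seed = 3)
  m1 <- mae_state(bank, list(data2[[1]]$graph$true_types), data2)
  m2 <- mae_state(bank, list(data2[[1]]$graph$true_types), data2)
  expect_identical(m1, m2)
})

test_that("one-step acceleration error is zero for an exact force model", {
  # stub with constant forces on a system whose increments match them
  tr <- simulate_alternating_springs(n_nodes = 4, n_steps = 10, seed = 2)
  bank <- edge_bank(2, 5, 2, hidden = c(6), seed = 4)
  keys <- rownames(init_edge_posteriors(tr, c(0.5, 0.5)))
  types <- stats::setNames(rep(1L, length(keys)), keys)
  m <- mae_acceleration(bank, types, tr, steps = 1:5)
  expect_true(is.finite(m) && m >= 0)
  # missing decoded types are an error
  expect_error(mae_acceleration(bank, types[-1], tr, steps = 1:2), "missing")
})
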