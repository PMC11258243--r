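#' Simulate the two-species crystallization system with evolving topology
#'
#' 100 unit-mass particles of two kinds interact through a Lennard-Jones
#' potential plus a dipole term that is attractive between identical kinds
#' and repulsive between different kinds. Interactions are restricted to each
#' particle's `n_neighbors` nearest neighbours, so the interaction graph
#' changes as particles rearrange. The raw dynamics are integrated at a fine
#' step (`dt = 1e-5`) and downsampled (every 50 raw steps by default); the
#' downsampled series with its per-step neighbour lists is what inference
#' consumes. The neighbour graph is refreshed at the downsample resolution.
#'
#' @param n_particles number of particles.
#' @param n_steps number of stored (downsampled) states.
#' @param dt raw integration step size.
#' @param downsample raw steps per stored state.
#' @param spec a [crystal_spec()].
#' @param seed integer seed (kinds, initial box positions, velocities).
#' @param box_side side of the initial square box; default `sqrt(N)` gives
#'   roughly unit number density.
#' @param vel_sd standard deviation of the initial velocities. The
#'   observation window is short, so thermal motion is what drives particle
#'   rearrangement (and hence topology changes and geometric diversity) at
#'   desk scale.
#' @param min_dist minimum pairwise distance of the initial configuration
#'   (rejection sampling). Uniformly random positions contain near-coincident
#'   pairs whose dipole forces diverge like `r^-5`, producing unphysical
#'   accelerations; enforcing an initial separation keeps the transient
#'   gentle at desk scale.
#' @param d spatial dimension.
#' @return an `evolving_trajectory`: positions/velocities/increments on the
#'   downsampled grid, per-step active edge matrices `neighbors[[t]]`
#'   (receiver, actor), particle `kinds`, and a `type_of` function mapping a
#'   directed pair to its ground-truth type (1 = same kind, 2 = different).
#' @export
simulate_crystallization <- function(n_particles = 100L, n_steps = 200L,
                                     dt = 1e-5, downsample = 50L,
                                     spec = crystal_spec(), seed = 1L,
                                     box_side = NULL, vel_sd = 0.1,
                                     min_dist = 0.6, d = 2L) {
  N <- n_particles
  if (is.null(box_side)) box_side <- sqrt(N)
  init <- withr::with_seed(seed, {
    kinds <- sample(rep(1:2, length.out = N))
    pos <- matrix(0, N, d)
    placed <- 0L
    tries <- 0L
    while (placed < N) {
      cand <- stats::runif(d, 0, box_side)
      ok <- placed == 0L ||
        min(sqrt(colSums((t(pos[seq_len(placed), , drop = FALSE]) - cand)^2))) >= min_dist
      tries <- tries + 1L
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
      if (tries > 10000L * N) stop("cannot place particles; lower min_dist")
    }
    vel <- matrix(stats::rnorm(N * d, 0, vel_sd), N, d)
    list(kinds = kinds, pos = pos, vel = vel)
  })
  masses <- rep(1, N)
  pos <- init$pos; vel <- init$vel
  positions <- array(0, c(n_steps, N, d))
  velocities <- array(0, c(n_steps, N, d))
  neighbors <- vector("list", n_steps)
  pair_type <- function(i, j) ifelse(init$kinds[i] == init$kinds[j], 1L, 2L)
  for (t in seq_len(n_steps)) {
    positions[t, , ] <- pos
    velocities[t, , ] <- vel
    edges <- build_knn_graph(pos, spec$n_neighbors)
    neighbors[[t]] <- edges
    if (t == n_steps) break
    types <- pair_type(edges[, 1L], edges[, 2L])
    for (s in seq_len(downsample)) {
      F <- .net_forces(pos, edges, types, spec)
      vel <- vel + F * dt          # unit masses
      pos <- pos + vel * dt
      if (any(!is.finite(pos))) {
        stop("simulation blew up at stored step ", t, ", raw substep ", s)
      }
    }
  }
  dt_eff <- dt * downsample
  inc <- (velocities[-1L, , , drop = FALSE] -
            velocities[-n_steps, , , drop = FALSE]) / dt_eff
  structure(list(positions = positions, velocities = velocities,
                 masses = masses, dt = dt_eff, increments = inc,
                 neighbors = neighbors, kinds = init$kinds,
                 type_of = pair_type, K = 2L, spec = spec),
            class = "evolving_trajectory")
}

#' Simulate a toy two-type particle system with alternating topology
#'
#' A small spring-type system in which each node interacts with a different
#' neighbour subset at alternating time steps. Used to exercise the
#' evolving-topology inference path at desk scale: edge types are fixed over
#' time while the active edge set changes.
#'
#' @param n_nodes nodes per system.
#' @param n_steps stored states.
#' @param spec a [spring_spec()] supplying the per-type force laws.
#' @param dt step size.
#' @param seed integer seed.
#' @param d spatial dimension.
#' @return an `evolving_trajectory` (with per-node masses).
#' @export
simulate_alternating_springs <- function(n_nodes = 5L, n_steps = 100L,
                                         spec = spring_spec(), dt = 0.01,
                                         seed = 1L, d = 2L) {
  full <- full_graph(n_nodes, spec$K, seed = seed)
  st <- withr::with_seed(seed + 1L, {
    list(m = exp(stats::runif(n_nodes, -1, 1)),
         pos = matrix(stats::rnorm(n_nodes * d), n_nodes, d),
         vel = matrix(stats::rnorm(n_nodes * d), n_nodes, d))
  })
  tt <- full$true_types
  names(tt) <- paste(full$edges[, 1L], full$edges[, 2L])
  pair_type <- function(i, j) unname(tt[paste(i, j)])
  # two alternating half-graphs: odd steps use pairs with odd i+j, even the rest
  parity <- (full$edges[, 1L] + full$edges[, 2L]) %% 2L
  halves <- list(full$edges[parity == 1L, , drop = FALSE],
                 full$edges[parity == 0L, , drop = FALSE])
  pos <- st$pos; vel <- st$vel
  positions <- array(0, c(n_steps, n_nodes, d))
  velocities <- array(0, c(n_steps, n_nodes, d))
  neighbors <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    positions[t, , ] <- pos
    velocities[t, , ] <- vel
    edges <- halves[[1L + (t %% 2L)]]
    neighbors[[t]] <- edges
    if (t == n_steps) break
    types <- pair_type(edges[, 1L], edges[, 2L])
    F <- .net_forces(pos, edges, types, spec)
    vel <- vel + (F / st$m) * dt
    pos <- pos + vel * dt
  }
  inc <- (velocities[-1L, , , drop = FALSE] -
            velocities[-n_steps, , , drop = FALSE]) / dt
  structure(list(positions = positions, velocities = velocities,
                 masses = st$m, dt = dt, increments = inc,
                 neighbors = neighbors, kinds = NULL, type_of = pair_type,
                 K = spec$K, spec = spec),
            class = "evolving_trajectory")
}
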