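#' Force-law specifications for the particle simulators
#'
#' Construct the specification of a heterogeneous particle system. The
#' defaults follow the benchmark settings used throughout the package: two
#' spring types `(k, L) = (0.5, 2.0)` and `(2.0, 1.0)`; unit-constant charge
#' forces softened by `delta = 0.01`; Lennard-Jones plus dipole interactions
#' with `sigma_lj = 0.3`, `eps_lj = 1e-5`, `C_dip = 0.02` among each
#' particle's five nearest neighbours.
#'
#' @param spring_k,spring_L per-type stiffnesses and balance lengths.
#' @return a `force_spec` list.
#' @export
spring_spec <- function(spring_k = c(0.5, 2.0), spring_L = c(2.0, 1.0)) {
  stopifnot(length(spring_k) == length(spring_L), all(spring_k >= 0))
  structure(list(kind = "spring", K = length(spring_k),
                 k = spring_k, L = spring_L), class = "force_spec")
}

#' @rdname spring_spec
#' @param c_const,delta charge-force constant and distance softening.
#' @export
charge_spec <- function(c_const = 1, delta = 0.01) {
  stopifnot(c_const > 0, delta > 0)
  structure(list(kind = "charge", K = 2L, c_const = c_const, delta = delta),
            class = "force_spec")
}

#' @rdname spring_spec
#' @param sigma_lj,eps_lj,C_dip Lennard-Jones and dipole constants.
#' @param n_neighbors neighbours each particle interacts with.
#' @export
crystal_spec <- function(sigma_lj = 0.3, eps_lj = 1e-5, C_dip = 0.02,
                         n_neighbors = 5L) {
  stopifnot(sigma_lj > 0, eps_lj > 0, C_dip > 0, n_neighbors >= 1)
  structure(list(kind = "crystal", K = 2L, sigma_lj = sigma_lj,
                 eps_lj = eps_lj, C_dip = C_dip,
                 n_neighbors = as.integer(n_neighbors)),
            class = "force_spec")
}

# per-edge ground-truth forces (force on the receiver), vectorized over edges
.edge_forces <- function(pos, edges, types, spec, extra = NULL) {
  dvec <- pos[edges[, 2L], , drop = FALSE] - pos[edges[, 1L], , drop = FALSE]
  r <- sqrt(rowSums(dvec * dvec))
  if (any(r == 0)) stop("coincident positions: pairwise force is undefined")
  n_ij <- dvec / r
  mag <- switch(spec$kind,
    spring = spec$k[types] * (r - spec$L[types]),
    charge = {
      qq <- extra$charges[edges[, 1L]] * extra$charges[edges[, 2L]]
      -spec$c_const * qq / (r + spec$delta)^2
    },
    crystal = {
      sr6 <- (spec$sigma_lj / r)^6
      dVlj <- 4 * spec$eps_lj * (-12 * sr6 * sr6 + 6 * sr6) / r
      same <- types == 1L
      dVlj + ifelse(same, 4, -4) * spec$C_dip / r^5
    },
    stop("unknown force kind: ", spec$kind))
  mag * n_ij
}

# net force on every node given one configuration
.net_forces <- function(pos, edges, types, spec, extra = NULL) {
  N <- nrow(pos)
  d <- ncol(pos)
  F <- matrix(0, N, d)
  if (!nrow(edges)) return(F)
  fe <- .edge_forces(pos, edges, types, spec, extra)
  idx <- edges[, 1L]
  for (col in seq_len(d)) {
    sums <- rowsum(fe[, col], idx)   # rows named by sorted receiver index
    F[as.integer(rownames(sums)), col] <- sums
  }
  F
}

#' Particle trajectory container
#'
#' @param positions,velocities `T x N x d` arrays of states.
#' @param masses length-`N` vector of strictly positive masses.
#' @param dt integration step between stored states.
#' @param increments optional `(T-1) x N x d` array of ground-truth state
#'   increments; computed by [ground_truth_increments()] when omitted.
#' @return a `particle_trajectory` object.
#' @export
particle_trajectory <- function(positions, velocities, masses, dt,
                                increments = NULL) {
  stopifnot(identical(dim(positions), dim(velocities)),
            length(dim(positions)) == 3L, dim(positions)[1L] >= 2L,
            length(masses) == dim(positions)[2L], all(masses > 0), dt > 0)
  obj <- structure(list(positions = positions, velocities = velocities,
                        masses = masses, dt = dt, increments = increments),
                   class = "particle_trajectory")
  if (is.null(increments)) obj$increments <- ground_truth_increments(obj)
  obj
}

#' Ground-truth state increments of a trajectory
#'
#' Finite-difference accelerations `(v[t+1] - v[t]) / dt` for
#' `t = 1..T-1`. Under the semi-implicit Euler integrator used by the
#' simulators these equal the accelerations actually applied at each step, so
#' they are exact regression targets rather than approximations.
#'
#' @param trajectory a `particle_trajectory`.
#' @return `(T-1) x N x d` array.
#' @export
ground_truth_increments <- function(trajectory) {
  v <- trajectory$velocities
  T_ <- dim(v)[1L]
  stopifnot(T_ >= 2L)
  inc <- (v[-1L, , , drop = FALSE] - v[-T_, , , drop = FALSE]) / trajectory$dt
  inc
}

#' Integrate Newtonian dynamics of a static-topology particle system
#'
#' Semi-implicit (symplectic) Euler: `v <- v + (F/m) dt`, then
#' `r <- r + v dt`. The applied accelerations are logged as the trajectory's
#' ground-truth increments. Bitwise reproducible for a fixed seed.
#'
#' @param spec a `force_spec` (spring or charge).
#' @param graph an [interaction_graph()] carrying ground-truth edge types.
#' @param n_steps number of stored states `T`.
#' @param dt step size.
#' @param seed integer seed for masses and initial conditions.
#' @param d spatial dimension (default 2).
#' @param charges per-particle charges (charge systems only; drawn at
#'   random when omitted).
#' @return `particle_trajectory` (with `charges` attached for charge runs).
#' @export
simulate_particles <- function(spec, graph, n_steps = 100L, dt = 0.01,
                               seed = 1L, d = 2L, charges = NULL) {
  N <- graph$n_nodes
  state <- withr::with_seed(seed, {
    m <- exp(stats::runif(N, -1, 1))            # log-uniform masses
    pos <- matrix(stats::rnorm(N * d), N, d)     # standard Gaussian init
    vel <- matrix(stats::rnorm(N * d), N, d)
    q <- if (spec$kind == "charge" && is.null(charges)) {
      sample(c(-1, 1), N, replace = TRUE)
    } else charges
    list(m = m, pos = pos, vel = vel, q = q)
  })
  positions <- array(0, c(n_steps, N, d))
  velocities <- array(0, c(n_steps, N, d))
  increments <- array(0, c(n_steps - 1L, N, d))
  pos <- state$pos; vel <- state$vel
  positions[1L, , ] <- pos; velocities[1L, , ] <- vel
  extra <- list(charges = state$q)
  for (t in seq_len(n_steps - 1L)) {
    F <- .net_forces(pos, graph$edges, graph$true_types, spec, extra)
    a <- F / state$m
    vel <- vel + a * dt
    pos <- pos + vel * dt
    if (any(!is.finite(pos)) || any(!is.finite(vel))) {
      stop("simulation blew up at step ", t + 1L)
    }
    positions[t + 1L, , ] <- pos
    velocities[t + 1L, , ] <- vel
    increments[t, , ] <- a
  }
  traj <- particle_trajectory(positions, velocities, state$m, dt, increments)
  traj$charges <- state$q
  traj
}

#' Simulate benchmark datasets of heterogeneous particle systems
#'
#' `simulate_springs()` draws fully connected systems whose unordered pairs
#' are linked by one of `K` spring types; `simulate_charges()` draws systems
#' of unit charges of random sign (two effective edge types: repulsive for
#' like, attractive for unlike charges). Each simulation has its own edge
#' types, masses and initial conditions; defaults are 100 stored states at
#' step size 0.01.
#'
#' @param n_sims number of independent simulations.
#' @param n_nodes particles per simulation.
#' @param spec force specification ([spring_spec()] / [charge_spec()]).
#' @inheritParams simulate_particles
#' @return an `ri_dataset`: list of `list(trajectory, graph)` pairs.
#' @export
simulate_springs <- function(n_sims, n_nodes = 5L, spec = spring_spec(),
                             n_steps = 100L, dt = 0.01, seed = 1L, d = 2L) {
  seeds <- .spawn_seeds(seed, 2L * n_sims)
  sims <- lapply(seq_len(n_sims), function(s) {
    graph <- full_graph(n_nodes, spec$K, seed = seeds[2L * s - 1L])
    traj <- simulate_particles(spec, graph, n_steps, dt, seed = seeds[2L * s], d = d)
    list(trajectory = traj, graph = graph)
  })
  structure(sims, class = "ri_dataset", spec = spec)
}

#' @rdname simulate_springs
#' @export
simulate_charges <- function(n_sims, n_nodes = 5L, spec = charge_spec(),
                             n_steps = 100L, dt = 0.01, seed = 1L, d = 2L) {
  seeds <- .spawn_seeds(seed, n_sims)
  sims <- lapply(seq_len(n_sims), function(s) {
    base <- interaction_graph(n_nodes, .all_pairs(n_nodes), K = 2L)
    traj <- simulate_particles(spec, within_types(base), n_steps, dt,
                               seed = seeds[s], d = d)
    q <- traj$charges
    tt <- ifelse(q[base$edges[, 1L]] * q[base$edges[, 2L]] > 0, 1L, 2L)
    graph <- interaction_graph(n_nodes, base$edges, true_types = tt, K = 2L)
    list(trajectory = traj, graph = graph)
  })
  structure(sims, class = "ri_dataset", spec = spec)
}

# charge forces depend on the charges themselves, not on stored edge types;
# give the integrator a placeholder typing
within_types <- function(graph) {
  graph$true_types <- rep(1L, nrow(graph$edges))
  graph
}

.all_pairs <- function(n) {
  p <- t(utils::combn(n, 2L))
  rbind(p, p[, 2:1, drop = FALSE])
}

.spawn_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
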