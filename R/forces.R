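#' Pairwise force laws of the benchmark particle systems
#'
#' All forces follow the receiver convention of the interaction graph: the
#' directed edge (i, j) means "node j acts on node i", and every force
#' returned here is the force exerted ON node i BY node j. Under this reading
#' a stretched spring pulls i towards j and like charges push i away from j,
#' and all three laws are exactly antisymmetric under exchanging the two
#' particles (Newton's third law).
#'
#' @name pairwise_forces
NULL

.unit_sep <- function(pos_i, pos_j) {
  dvec <- pos_j - pos_i
  r <- sqrt(sum(dvec * dvec))
  if (r == 0) stop("coincident positions: pairwise force is undefined")
  list(r = r, n = dvec / r)
}

#' @rdname pairwise_forces
#' @param pos_i,pos_j positions of the receiver i and the actor j
#'   (numeric vectors of equal length).
#' @param k spring stiffness (> 0).
#' @param L spring balance length.
#' @return force on node i (numeric vector).
#' @examples
#' spring_force(c(0, 0), c(2, 0), k = 2, L = 1)   # (2, 0): i pulled toward j
#' @export
spring_force <- function(pos_i, pos_j, k, L) {
  s <- .unit_sep(pos_i, pos_j)
  k * (s$r - L) * s$n
}

#' @rdname pairwise_forces
#' @param q_i,q_j charges, each +1 or -1.
#' @param c_const Coulomb-like constant (default 1).
#' @param delta softening added to the distance in the denominator only
#'   (default 0.01); the direction uses the unsoftened separation.
#' @export
charge_force <- function(pos_i, pos_j, q_i, q_j, c_const = 1, delta = 0.01) {
  if (!(q_i %in% c(-1, 1)) || !(q_j %in% c(-1, 1))) {
    stop("charges must be +1 or -1")
  }
  s <- .unit_sep(pos_i, pos_j)
  -c_const * q_i * q_j * s$n / (s$r + delta)^2
}

#' @rdname pairwise_forces
#' @param same_type logical; `TRUE` when the two particles are of the same
#'   kind (attractive dipole term), `FALSE` otherwise (repulsive).
#' @param sigma_lj,eps_lj Lennard-Jones length and energy scales.
#' @param C_dip dipole potential constant; the dipole potential is
#'   `-C/r^4` for identical kinds and `+C/r^4` for different kinds.
#' @export
crystal_force <- function(pos_i, pos_j, same_type,
                          sigma_lj = 0.3, eps_lj = 1e-5, C_dip = 0.02) {
  s <- .unit_sep(pos_i, pos_j)
  r <- s$r
  # radial derivative of V_LJ(r) = 4 eps ((s/r)^12 - (s/r)^6)
  sr6 <- (sigma_lj / r)^6
  dVlj <- 4 * eps_lj * (-12 * sr6 * sr6 + 6 * sr6) / r
  # dipole: V = -C r^-4 (same kind) or +C r^-4 (different kinds)
  dVdip <- if (same_type) 4 * C_dip / r^5 else -4 * C_dip / r^5
  # force on i = -dV/dr * (dr/d r_i) = +dV/dr * n_ij
  (dVlj + dVdip) * s$n
}

#' Potentials matching the crystallization force law
#'
#' Scalar potentials used by the simulators for energy bookkeeping and by the
#' test-suite finite-difference oracles.
#'
#' @param r inter-particle distance (> 0).
#' @inheritParams pairwise_forces
#' @return potential energy (scalar, vectorized over `r`).
#' @export
crystal_potential <- function(r, same_type,
                              sigma_lj = 0.3, eps_lj = 1e-5, C_dip = 0.02) {
  sr6 <- (sigma_lj / r)^6
  v <- 4 * eps_lj * (sr6 * sr6 - sr6)
  v + if (same_type) -C_dip / r^4 else C_dip / r^4
}

#' @rdname crystal_potential
#' @export
spring_potential <- function(r, k, L) 0.5 * k * (r - L)^2
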