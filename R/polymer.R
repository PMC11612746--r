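# Bead-spring polymer: FENE bonds, WCA excluded volume, nematic-polymer
# coupling, and a plain velocity-Verlet integrator for isolated chains.

#' FENE bond energy and force
#'
#' Finitely extensible nonlinear elastic bond,
#' `V = -(k_FENE r0^2 / 2) ln(1 - (r/r0)^2)`: harmonic at small extension,
#' divergent restoring force as `r -> r0`.
#'
#' @param r bond length(s), must satisfy `0 < r < r0`.
#' @param k_FENE bond strength (kBT/a^2).
#' @param r0 divergence radius of the closed form (a).  The simulated
#'   chain uses `r_max = 1.5 a` here (see [sim_config()]), which together
#'   with the WCA repulsion puts the canonical mean bond length at 0.89 a.
#' @return list with `energy` and `force`, the signed radial force
#'   `-dV/dr` on the far bead along the bond direction (negative =
#'   attractive); the partner bead feels the opposite force.
#' @export
fene_energy_force <- function(r, k_FENE = 120, r0 = 1) {
  if (any(r <= 0)) stop("FENE bond length must be positive")
  if (any(r >= r0)) {
    stop("FENE bond length r = ", max(r), " >= r0 = ", r0,
         ": beyond the divergence radius (MD timestep too large?)")
  }
  w <- 1 - (r / r0)^2
  list(energy = -(k_FENE * r0^2 / 2) * log(w),
       force = -k_FENE * r / w)
}

#' WCA (purely repulsive Lennard-Jones) energy and force
#'
#' `V = 4 eps [ (sigma/r)^12 - (sigma/r)^6 ] + eps` for
#' `r < 2^(1/6) sigma`, exactly zero beyond; continuous at the cutoff.
#'
#' @param r pair distance(s), `> 0`.
#' @param epsilon repulsion strength (kBT).
#' @param sigma bead diameter (a).
#' @return list with `energy` and `force` (`-dV/dr`, positive = repulsive).
#' @export
wca_energy_force <- function(r, epsilon = 1, sigma = 1) {
  if (any(r <= 0)) stop("WCA distance must be positive (bead overlap)")
  rc <- 2^(1 / 6) * sigma
  s6 <- (sigma / r)^6
  inside <- r < rc
  energy <- ifelse(inside, 4 * epsilon * (s6^2 - s6) + epsilon, 0)
  force <- ifelse(inside, 24 * epsilon * (2 * s6^2 - s6) / r, 0)
  list(energy = energy, force = force)
}

#' Nematic-polymer coupling energy, forces and torque for one bond
#'
#' Harmonic angular potential `V = k theta^2 / 2` between the bond tangent
#' `t` and the local director `n`, with the acute (head-tail symmetric)
#' angle `theta = arccos(|t . n|)` in `[0, pi/2]`: a bond anti-parallel to
#' the director is as unpenalized as a parallel one, which is what permits
#' hairpins (two anti-aligned arms, both relaxed).  The restoring torque on
#' the bond is `tau = k theta` about the axis `t x n`; the equal-but-
#' opposite torque belongs to the mesogens of the local cell (see
#' [bond_torque_on_cell()]).
#'
#' @param r_j,r_l positions of the bonded beads (the tangent points from
#'   `l` to `j`; `j` is the bead whose cell supplies the director).
#' @param n_c local director (unit).
#' @param k coupling constant (kBT).
#' @return list with `energy`, `force_j`, `force_l` (3-vectors, equal and
#'   opposite, perpendicular to the bond), `torque` (magnitude `k theta`),
#'   `axis` (unit rotation axis `t x n`, zero when `t` is parallel to `n`)
#'   and `theta`.
#' @export
npc_energy_force <- function(r_j, r_l, n_c, k) {
  d <- r_j - r_l
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("zero-length bond in nematic-polymer coupling")
  t <- d / r
  cth <- sum(t * n_c)
  neff <- if (cth < 0) -n_c else n_c
  cth <- min(abs(cth), 1)
  theta <- acos(cth)
  sth <- sqrt(max(0, 1 - cth^2))
  pref <- if (sth > 1e-8) k * theta / sth else k
  fj <- pref * (neff - cth * t) / r
  ax <- c(t[2] * neff[3] - t[3] * neff[2],
          t[3] * neff[1] - t[1] * neff[3],
          t[1] * neff[2] - t[2] * neff[1])
  na <- sqrt(sum(ax^2))
  list(energy = k * theta^2 / 2,
       force_j = fj, force_l = -fj,
       torque = k * theta,
       axis = if (na > 1e-12) ax / na else c(0, 0, 0),
       theta = theta)
}

#' Total forces on an isolated chain
#'
#' FENE + WCA (+ optional nematic coupling against a fixed director) for a
#' free chain; used for integrator checks and small fixtures (no solvent,
#' no periodic images).
#'
#' @param pos N x 3 bead positions.
#' @param k_FENE,r0,epsilon,sigma,k potential parameters.
#' @param director fixed director for the coupling term (used when
#'   `k > 0`).
#' @return list with `forces` (N x 3) and energies by term.
#' @export
chain_forces <- function(pos, k_FENE = 120, r0 = 1.5, epsilon = 1, sigma = 1,
                         k = 0, director = c(0, 0, 1)) {
  N <- nrow(pos)
  F <- matrix(0, N, 3)
  e_fene <- e_wca <- e_npc <- 0
  for (j in seq_len(N - 1)) {
    d <- pos[j + 1, ] - pos[j, ]
    r <- sqrt(sum(d^2))
    ff <- fene_energy_force(r, k_FENE, r0)
    e_fene <- e_fene + ff$energy
    F[j + 1, ] <- F[j + 1, ] + ff$force * d / r
    F[j, ] <- F[j, ] - ff$force * d / r
  }
  if (N >= 2) {
    for (i in seq_len(N - 1)) {
      for (j in seq((i + 1), N)) {
        d <- pos[i, ] - pos[j, ]
        r <- sqrt(sum(d^2))
        wf <- wca_energy_force(r, epsilon, sigma)
        if (wf$energy > 0 || wf$force != 0) {
          e_wca <- e_wca + wf$energy
          F[i, ] <- F[i, ] + wf$force * d / r
          F[j, ] <- F[j, ] - wf$force * d / r
        }
      }
    }
  }
  if (k > 0) {
    for (j in seq_len(N - 1)) {
      nf <- npc_energy_force(pos[j + 1, ], pos[j, ], director, k)
      e_npc <- e_npc + nf$energy
      F[j + 1, ] <- F[j + 1, ] + nf$force_j
      F[j, ] <- F[j, ] + nf$force_l
    }
  }
  list(forces = F, e_fene = e_fene, e_wca = e_wca, e_npc = e_npc)
}

#' Velocity-Verlet integration of an isolated system
#'
#' Plain symplectic velocity Verlet `x(t + dt)` update, suitable for
#' integrator checks (energy drift, time reversibility).  The force
#' callback receives positions and returns an N x 3 matrix.
#'
#' @param pos,vel N x 3 initial positions and velocities.
#' @param mass bead mass (scalar or length N).
#' @param force_fn function(pos) -> N x 3 forces.
#' @param dt timestep.
#' @param nsteps number of steps.
#' @return list with final `pos`, `vel`.
#' @export
md_verlet <- function(pos, vel, mass, force_fn, dt, nsteps) {
  mass <- rep_len(mass, nrow(pos))
  F <- force_fn(pos)
  if (!all(is.finite(F))) stop("non-finite force at initialization")
  for (s in seq_len(nsteps)) {
    vel <- vel + F * dt / (2 * mass)
    pos <- pos + vel * dt
    F <- force_fn(pos)
    if (!all(is.finite(F))) stop("non-finite force at step ", s)
    vel <- vel + F * dt / (2 * mass)
  }
  list(pos = pos, vel = vel)
}
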