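# Reference implementations of the N-MPCD solvent operations.  These are
# the documented, testable definitions of each algorithmic ingredient; the
# production loop in run_simulation() executes the same physics in compiled
# code.

#' Ballistic streaming
#'
#' Advances positions by `r + v dt`; velocities and orientations are
#' untouched.
#'
#' @param r n x 3 position matrix.
#' @param v n x 3 velocity matrix.
#' @param dt streaming step.
#' @return Updated position matrix.
#' @export
stream_particles <- function(r, v, dt) {
  if (!all(is.finite(v))) stop("non-finite velocity in streaming step")
  r + v * dt
}

#' Grid-shifted cell assignment
#'
#' Bins particles into cubic cells of edge `a = 1` in the shifted frame:
#' the cell index of a particle is `floor(r + shift)` per component (cells
#' are half-open, `[0, 1)`).  The random grid shift restores Galilean
#' invariance; it applies to the binning only, never to stored positions.
#'
#' @param r n x d position matrix.
#' @param shift length-d grid shift (each component in `[-1/2, 1/2)`).
#' @param box optional length-d box for periodic wrapping of the shifted
#'   coordinate.
#' @return n x d integer matrix of cell indices.
#' @export
bin_with_grid_shift <- function(r, shift = rep(0, ncol(r)), box = NULL) {
  s <- sweep(r, 2, shift, "+")
  if (!is.null(box)) {
    s <- sweep(s, 2, box, function(x, L) x - L * floor(x / L))
  }
  idx <- floor(s)
  storage.mode(idx) <- "integer"
  idx
}

#' Andersen-thermostatted velocity collision for one cell
#'
#' Draws fresh Maxwell-Boltzmann velocities at temperature `kBT` for every
#' member and restores the cell centre-of-mass velocity, so that cell
#' linear momentum is conserved exactly:
#' `v' = v_cm + xi - <xi>` with the mass-weighted mean `<xi>`.  With
#' `angular = TRUE` a rigid-body rotation about the cell centre of mass is
#' added to restore the cell's angular momentum as well (the variant whose
#' collisional viscosity matches this solvent's calibration).
#'
#' @param v n x 3 member velocities.
#' @param mass member masses (length n or scalar); monomers participate
#'   with their own mass.
#' @param kBT thermal energy.
#' @param pos n x 3 member positions (required for `angular = TRUE`).
#' @param angular restore cell angular momentum (default TRUE).
#' @param xi optional n x 3 matrix of pre-drawn normal(0,1) deviates
#'   (deterministic testing); defaults to `rnorm`.
#' @return n x 3 matrix of post-collision velocities.
#' @export
andersen_velocity_collision <- function(v, mass, kBT = 1, pos = NULL,
                                        angular = TRUE, xi = NULL) {
  n <- nrow(v)
  mass <- rep_len(mass, n)
  if (n == 1) return(v)
  if (is.null(xi)) xi <- matrix(rnorm(3 * n), n, 3)
  xi <- xi * sqrt(kBT / mass)
  M <- sum(mass)
  vcm <- colSums(v * mass) / M
  xim <- colSums(xi * mass) / M
  vnew <- sweep(sweep(xi, 2, xim, "-"), 2, vcm, "+")
  if (angular) {
    if (is.null(pos)) stop("pos required to restore angular momentum")
    com <- colSums(pos * mass) / M
    dr <- sweep(pos, 2, com, "-")
    dv <- v - vnew
    L <- colSums(mass * cbind(dr[, 2] * dv[, 3] - dr[, 3] * dv[, 2],
                              dr[, 3] * dv[, 1] - dr[, 1] * dv[, 3],
                              dr[, 1] * dv[, 2] - dr[, 2] * dv[, 1]))
    r2 <- rowSums(dr^2)
    I <- matrix(0, 3, 3)
    for (al in 1:3) {
      for (be in 1:3) {
        I[al, be] <- sum(mass * ((al == be) * r2 - dr[, al] * dr[, be]))
      }
    }
    w <- tryCatch(solve(I, L), error = function(e) NULL)
    if (!is.null(w)) {
      vnew <- vnew + cbind(w[2] * dr[, 3] - w[3] * dr[, 2],
                           w[3] * dr[, 1] - w[1] * dr[, 3],
                           w[1] * dr[, 2] - w[2] * dr[, 1])
    }
  }
  vnew
}

#' Cell director and scalar order parameter
#'
#' Builds the cell orientation tensor
#' `Q = (d/(d-1)) (<u u> - I/d)` over the member orientations and returns
#' its largest eigenvalue (the scalar order parameter `S`) and the
#' corresponding eigenvector (the director `n`, defined up to sign; the
#' sign is fixed so the first nonzero component is positive).
#'
#' @param u n x d matrix of unit orientations.
#' @param d dimensionality (2 or 3), default `ncol(u)`.
#' @return list with `S`, `director`, and the tensor `Q`.
#' @export
cell_order_parameters <- function(u, d = ncol(u)) {
  if (nrow(u) < 1) stop("empty cell")
  M2 <- crossprod(u) / nrow(u)
  Q <- (d / (d - 1)) * (M2 - diag(ncol(u)) / d)
  e <- eigen(Q, symmetric = TRUE)
  S <- e$values[1]
  n <- e$vectors[, 1]
  nz <- which(abs(n) > 1e-12)[1]
  if (!is.na(nz) && n[nz] < 0) n <- -n
  list(S = S, director = n, Q = Q)
}

#' Sample the Maier-Saupe orientation distribution
#'
#' Draws orientations from the canonical single-particle distribution about
#' a director `n`, with density proportional to `exp(a (u . n)^2)` on the
#' unit sphere (circle for `d = 2`).  In the collision step the alignment
#' parameter is `a = (d/(d-1)) U S_c / kBT`, i.e. the Maier-Saupe weight
#' `exp(U S_c P2(u.n) / kBT)` up to a constant, which places the 3D
#' isotropic-nematic transition near `U ~ 5` so that `U = 6` is nematic.
#' The density is head-tail symmetric by construction.
#'
#' @param n_draws number of orientations.
#' @param a alignment parameter (dimensionless; may be negative).
#' @param director unit director.
#' @param d dimensionality (2 or 3).
#' @param seed stream seed.
#' @return `n_draws` x 3 matrix of unit vectors (third column zero in 2D).
#' @export
sample_maier_saupe <- function(n_draws, a, director = c(0, 0, 1), d = 3,
                               seed = 1) {
  cpp_maier_saupe_draws(as.integer(n_draws), a, as.numeric(director),
                        as.integer(d), as.integer(seed))
}

#' Alignment parameter of the orientation collision
#'
#' @param U nematic interaction constant (kBT).
#' @param S local scalar order parameter.
#' @param d dimensionality.
#' @param kBT thermal energy.
#' @return `a = (d/(d-1)) U S / kBT`.
#' @export
maier_saupe_alignment <- function(U, S, d = 3, kBT = 1) {
  (d / (d - 1)) * U * S / kBT
}

#' Least-squares cell velocity gradient
#'
#' Fits `v ~ v0 + G (r - rbar)` over cell members by ordinary least
#' squares; used to estimate the local velocity-gradient tensor that
#' drives the Jeffery orientation update.  Requires at least `d + 1`
#' members in general position.
#'
#' @param pos n x 3 member positions.
#' @param vel n x 3 member velocities.
#' @return 3 x 3 velocity-gradient matrix `G` with `G[i, j] = d v_i / d x_j`.
#' @export
velocity_gradient_fit <- function(pos, vel) {
  n <- nrow(pos)
  if (n < 4) stop("velocity-gradient fit needs at least d + 1 = 4 members")
  X <- cbind(1, sweep(pos, 2, colMeans(pos), "-"))
  coefs <- tryCatch(qr.solve(X, vel), error = function(e) {
    stop("singular velocity-gradient fit (members in degenerate position)")
  })
  t(coefs[-1, , drop = FALSE])
}

#' Jeffery orientation update
#'
#' Rotates orientations in a velocity gradient following Jeffery's
#' equation for elongated particles:
#' `du = alpha dt [ W u + lambda (E u - (u . E . u) u) ]`, with `E` and `W`
#' the symmetric and antisymmetric parts of the velocity gradient, `lambda`
#' the bare tumbling parameter and `alpha` the shear susceptibility that
#' scales the alignment response; the result is renormalized.
#'
#' @param u n x 3 matrix of unit orientations.
#' @param G 3 x 3 velocity gradient (`G[i, j] = d v_i / d x_j`).
#' @param lambda bare tumbling parameter.
#' @param alpha shear susceptibility.
#' @param dt time step.
#' @return n x 3 matrix of updated unit orientations.
#' @export
jeffery_orientation_update <- function(u, G, lambda, alpha, dt) {
  E <- (G + t(G)) / 2
  W <- (G - t(G)) / 2
  Eu <- u %*% t(E)
  Wu <- u %*% t(W)
  uEu <- rowSums(u * Eu)
  un <- u + alpha * dt * (Wu + lambda * (Eu - uEu * u))
  un / sqrt(rowSums(un^2))
}

#' Backflow compensation for one cell
#'
#' Returns the rigid-body velocity correction that balances the angular
#' momentum `gamma_R * sum(d theta)` imparted to the director field by the
#' orientation collision: the opposite angular impulse is applied to the
#' cell members as a rotation about the cell centre of mass, which leaves
#' the cell linear momentum unchanged exactly.
#'
#' @param pos n x 3 member positions.
#' @param mass member masses (length n or scalar).
#' @param u_old,u_new m x 3 mesogen orientations before/after the
#'   orientation collision (nematic sign handled internally).
#' @param gamma_R rotational friction coefficient.
#' @return n x 3 matrix of velocity corrections (to be added to member
#'   velocities).
#' @export
backflow_compensation <- function(pos, mass, u_old, u_new, gamma_R) {
  n <- nrow(pos)
  mass <- rep_len(mass, n)
  dL <- c(0, 0, 0)
  for (i in seq_len(nrow(u_old))) {
    a <- u_old[i, ]
    b <- u_new[i, ]
    if (sum(a * b) < 0) b <- -b
    cx <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    sn <- sqrt(sum(cx^2))
    if (sn > 1e-12) {
      ang <- atan2(sn, sum(a * b))
      dL <- dL + gamma_R * ang * cx / sn
    }
  }
  if (all(dL == 0) || n < 2) return(matrix(0, n, 3))
  com <- colSums(pos * mass) / sum(mass)
  dr <- sweep(pos, 2, com, "-")
  r2 <- rowSums(dr^2)
  I <- matrix(0, 3, 3)
  for (al in 1:3) for (be in 1:3) {
    I[al, be] <- sum(mass * ((al == be) * r2 - dr[, al] * dr[, be]))
  }
  w <- tryCatch(solve(I, -dL), error = function(e) NULL)
  if (is.null(w)) return(matrix(0, n, 3))
  cbind(w[2] * dr[, 3] - w[3] * dr[, 2],
        w[3] * dr[, 1] - w[1] * dr[, 3],
        w[1] * dr[, 2] - w[2] * dr[, 1])
}
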