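# Two-way coupling: the reaction torque from each polymer bond rotates the
# mesogens of the local collision cell.

#' Director kick from a bond's reaction torque
#'
#' The angular impulse `tau * dt` exerted by the nematic on a bond over one
#' MPCD step is returned to the `N_c` mesogens of the bond's cell with
#' opposite sign, apportioned uniformly: each mesogen rotates by
#' `d theta = tau * dt / (gamma_R * N_c)` about the axis `t x n`, in the
#' sense that brings the director toward the bond tangent.  Total angular
#' impulse of (bond + cell) is zero by construction.
#'
#' @param tau torque magnitude `k theta` on the bond (kBT).
#' @param axis unit rotation axis `t x n` (from [npc_energy_force()]).
#' @param dt MPCD step over which the torque acted.
#' @param gamma_R rotational friction coefficient.
#' @param N_c number of mesogens in the cell; with `N_c = 0` the kick is
#'   dropped (empty cell).
#' @param apportion `"uniform"` divides the impulse equally over the
#'   mesogens (default); `"cell"` applies the whole angle to the cell as
#'   one rigid rotation (sensitivity variant).
#' @return list with `angle` (radians, per mesogen), `axis` (the kick axis,
#'   opposite to the bond torque axis), and `angular_impulse` (3-vector on
#'   the cell; equal and opposite to the bond's).
#' @export
bond_torque_on_cell <- function(tau, axis, dt, gamma_R, N_c,
                                apportion = c("uniform", "cell")) {
  apportion <- match.arg(apportion)
  if (N_c == 0) {
    return(list(angle = 0, axis = c(0, 0, 0), angular_impulse = c(0, 0, 0),
                dropped = TRUE))
  }
  J <- -tau * dt * axis # reaction: equal and opposite to the bond's impulse
  Jn <- sqrt(sum(J^2))
  denom <- if (apportion == "uniform") N_c else 1
  ang <- if (Jn > 0) Jn / (gamma_R * denom) else 0
  list(angle = ang,
       axis = if (Jn > 0) J / Jn else c(0, 0, 0),
       angular_impulse = J, dropped = FALSE)
}

#' Rotate unit vectors about an axis
#'
#' Rodrigues rotation of each row of `u` about the unit `axis` by `angle`.
#'
#' @param u n x 3 matrix of vectors.
#' @param axis unit rotation axis.
#' @param angle rotation angle (radians).
#' @return n x 3 matrix of rotated (renormalized) vectors.
#' @export
rotate_about_axis <- function(u, axis, angle) {
  if (angle == 0 || sqrt(sum(axis^2)) < 1e-12) return(u)
  k <- axis / sqrt(sum(axis^2))
  cs <- cos(angle); sn <- sin(angle)
  kxu <- cbind(k[2] * u[, 3] - k[3] * u[, 2],
               k[3] * u[, 1] - k[1] * u[, 3],
               k[1] * u[, 2] - k[2] * u[, 1])
  kd <- drop(u %*% k)
  un <- u * cs + kxu * sn + outer(kd * (1 - cs), k)
  un / sqrt(rowSums(un^2))
}

#' Apply accumulated director kicks to mesogen orientations
#'
#' Sums the kicks destined for each cell and rotates that cell's mesogens
#' by the net angle about the net axis; applied once per MPCD step, before
#' the orientation collision.
#'
#' @param u m x 3 mesogen orientations.
#' @param cell integer cell id per mesogen.
#' @param kicks data.frame with columns `cell`, `Jx`, `Jy`, `Jz`
#'   (angular-impulse components per kick).
#' @param gamma_R rotational friction coefficient.
#' @return m x 3 matrix of updated orientations.
#' @export
apply_director_kicks <- function(u, cell, kicks, gamma_R) {
  if (nrow(kicks) == 0) return(u)
  agg <- rowsum(as.matrix(kicks[, c("Jx", "Jy", "Jz")]), kicks$cell)
  for (ci in rownames(agg)) {
    J <- agg[ci, ]
    Jn <- sqrt(sum(J^2))
    if (Jn < 1e-15) next
    idx <- which(cell == as.integer(ci))
    if (length(idx) == 0) next
    ang <- Jn / (gamma_R * length(idx))
    u[idx, ] <- rotate_about_axis(u[idx, , drop = FALSE], J / Jn, ang)
  }
  u
}
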