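# Geometry: periodic boxes and the confining cylinder with perfect-slip,
# planar-anchored, impermeable walls capped by periodic boundaries.

#' Periodic wrapping
#'
#' Wraps coordinates into `[0, L)` per axis.  For the cylinder only the
#' axial coordinate is periodic.
#'
#' @param r n x d positions (or a vector).
#' @param box length-d box (use `NA` for non-periodic axes).
#' @return Wrapped coordinates.
#' @export
apply_periodic <- function(r, box) {
  wrap1 <- function(x, L) if (is.na(L)) x else x - L * floor(x / L)
  if (is.matrix(r)) {
    for (j in seq_len(ncol(r))) r[, j] <- wrap1(r[, j], box[j])
    r
  } else {
    mapply(wrap1, r, box)
  }
}

#' Minimum-image separation
#'
#' @param d separation vector(s) (n x d matrix or vector).
#' @param box length-d box (`NA` = non-periodic axis).
#' @return Minimum-image separation(s).
#' @export
min_image <- function(d, box) {
  mi1 <- function(x, L) if (is.na(L)) x else x - L * round(x / L)
  if (is.matrix(d)) {
    for (j in seq_len(ncol(d))) d[, j] <- mi1(d[, j], box[j])
    d
  } else {
    mapply(mi1, d, box)
  }
}

#' Perfect-slip reflection off the cylinder wall
#'
#' A particle whose straight-line displacement crossed the wall is brought
#' back inside by specular reflection at the crossing point: the velocity
#' component normal to the surface is negated, the tangential components
#' (including axial) are unchanged, so kinetic energy is conserved exactly.
#'
#' @param r_old position at the start of the streaming segment (inside).
#' @param r_new tentative position after streaming (possibly outside).
#' @param v velocity during the segment.
#' @param R cylinder radius (axis along z through the origin).
#' @return list with reflected `r` and `v`.
#' @export
reflect_perfect_slip <- function(r_old, r_new, v, R) {
  if (sqrt(sum(r_old[1:2]^2)) > R + 1) {
    stop("particle deeper than one cell beyond the wall: broken streaming step")
  }
  p <- r_old[1:2]
  q <- r_new[1:2] - r_old[1:2]
  z <- r_new[3]
  for (it in 1:5) {
    if (sum((p + q)^2) <= R^2) break
    aa <- sum(q^2)
    bb <- 2 * sum(p * q)
    cc <- sum(p^2) - R^2
    s <- if (aa < 1e-30) 1 else {
      disc <- max(bb^2 - 4 * aa * cc, 0)
      min(max((-bb + sqrt(disc)) / (2 * aa), 0), 1)
    }
    hit <- p + s * q
    nhat <- hit / sqrt(sum(hit^2))
    vn <- sum(v[1:2] * nhat)
    v[1:2] <- v[1:2] - 2 * vn * nhat
    rem <- (1 - s) * q
    rem <- rem - 2 * sum(rem * nhat) * nhat
    p <- hit
    q <- rem
  }
  xy <- p + q
  rr <- sqrt(sum(xy^2))
  if (rr > R) xy <- xy * (R * (1 - 1e-12)) / rr
  list(r = c(xy, z), v = v)
}

#' Initial extended conformation on the cylinder axis
#'
#' Beads placed collinearly on the centre line, aligned with the global
#' nematic direction (the cylinder axis), centred axially.
#'
#' @param N number of beads.
#' @param b bond spacing.
#' @param L axial length.
#' @return N x 3 position matrix.
#' @export
init_polymer_extended <- function(N, b = 0.9, L = 30) {
  if ((N - 1) * b >= L) stop("extended chain does not fit in the cylinder")
  z <- L / 2 + (seq_len(N) - (N + 1) / 2) * b
  cbind(0, 0, z)
}
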