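# Conformation observables: gyration tensor and its parallel/perpendicular
# decomposition, end-to-end scaling, tangent statistics, and the iterative
# steady-state onset detector.

#' Gyration tensor
#'
#' Second-moment tensor of bead positions about the centre of mass,
#' `G = < (r - r_cm)(r - r_cm) >` averaged over the N beads.  Positions
#' must be unwrapped (continuous across periodic boundaries).
#'
#' @param pos N x 3 matrix of unwrapped bead positions.
#' @param box optional length-3 box used only to detect wrapped input (a
#'   bond longer than half the box aborts).
#' @return 3 x 3 symmetric positive semi-definite matrix; `sum(diag(G))`
#'   is the squared radius of gyration.
#' @export
gyration_tensor <- function(pos, box = NULL) {
  if (nrow(pos) < 2) stop("gyration tensor needs at least 2 beads")
  if (!is.null(box)) {
    bl <- sqrt(rowSums(diff(pos)^2))
    if (any(bl > min(box, na.rm = TRUE) / 2)) {
      stop("bond longer than half the box: positions look wrapped, unwrap first")
    }
  }
  dr <- sweep(pos, 2, colMeans(pos), "-")
  crossprod(dr) / nrow(pos)
}

#' Decompose the gyration tensor along a director
#'
#' Parallel component `Rg_par^2 = n . G . n`; perpendicular component per
#' transverse direction `Rg_perp^2 = (G : (I - n n)) / 2`; aspect ratio
#' `beta = Rg_perp / Rg_par`.  The trace identity
#' `Rg^2 = Rg_par^2 + 2 Rg_perp^2` holds by construction.
#'
#' @param G 3 x 3 gyration tensor.
#' @param nhat unit director (default: the global nematic direction,
#'   `z`).
#' @return list with `Rg_par`, `Rg_perp`, `Rg`, `beta` (NA when
#'   `Rg_par = 0`).
#' @export
decompose_gyration <- function(G, nhat = c(0, 0, 1)) {
  nhat <- nhat / sqrt(sum(nhat^2))
  par2 <- drop(t(nhat) %*% G %*% nhat)
  perp2 <- (sum(diag(G)) - par2) / 2
  list(Rg_par = sqrt(max(par2, 0)),
       Rg_perp = sqrt(max(perp2, 0)),
       Rg = sqrt(max(sum(diag(G)), 0)),
       beta = if (par2 > 0) sqrt(max(perp2, 0) / par2) else NA_real_)
}

#' Radius of gyration of a straight rod
#'
#' Closed form for N beads with spacing b on a line:
#' `R_rod^2 = b^2 (N^2 - 1) / 12`.  Used to normalize the parallel
#' gyration component (`r_g_par = Rg_par / R_rod`).
#'
#' @param N number of beads.
#' @param b bond length.
#' @return `R_rod`.
#' @export
rod_gyration_radius <- function(N, b = 0.89) {
  sqrt(b^2 * (N^2 - 1) / 12)
}

#' Normalized end-to-end components
#'
#' The end-to-end vector `Re = r_N - r_1` split along and transverse to a
#' director, normalized by `N^nu b` with the scaling exponent `nu` (3/5
#' for a self-avoiding coil, 1 for a rod).
#'
#' @param pos N x 3 unwrapped positions.
#' @param nhat unit director.
#' @param nu scaling exponent.
#' @param b mean bond length.
#' @return list with `Re_par2`, `Re_perp2` (squared components) and
#'   `rho_par2`, `rho_perp2` (normalized by `(N^nu b)^2`).
#' @export
end_to_end_components <- function(pos, nhat = c(0, 0, 1), nu = 3 / 5,
                                  b = 0.89) {
  N <- nrow(pos)
  nhat <- nhat / sqrt(sum(nhat^2))
  Re <- pos[N, ] - pos[1, ]
  par2 <- sum(Re * nhat)^2
  perp2 <- sum(Re^2) - par2
  norm2 <- (N^nu * b)^2
  list(Re_par2 = par2, Re_perp2 = perp2,
       rho_par2 = par2 / norm2, rho_perp2 = perp2 / norm2)
}

#' Bond tangents of a chain
#'
#' @param pos N x 3 unwrapped positions.
#' @return (N-1) x 3 matrix of unit tangents `t_j = (r_{j+1} - r_j)/|...|`.
#' @export
bond_tangents <- function(pos) {
  d <- diff(pos)
  d / sqrt(rowSums(d^2))
}

#' Tangent statistics along the director
#'
#' Ensemble/time averages of `(t . n)^2` with
#' `<t_perp^2> = (1 - <(t . n)^2>)/2` (per transverse component), and a
#' block-averaged standard error.  The identity
#' `<t_par^2> + 2 <t_perp^2> = 1` holds exactly on every frame.
#'
#' @param tangents m x 3 matrix of unit tangents (stack frames over rows).
#' @param nhat unit director.
#' @param nblocks number of blocks for the standard error (default 10).
#' @return list with `t_par2`, `t_perp2`, `se` (standard error of
#'   `t_par2`).
#' @export
tangent_statistics <- function(tangents, nhat = c(0, 0, 1), nblocks = 10) {
  nhat <- nhat / sqrt(sum(nhat^2))
  proj2 <- drop(tangents %*% nhat)^2
  m <- mean(proj2)
  nb <- min(nblocks, length(proj2))
  blocks <- split(proj2, cut(seq_along(proj2), nb, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  list(t_par2 = m, t_perp2 = (1 - m) / 2,
       se = stats::sd(bm) / sqrt(length(bm)))
}

#' Iterative steady-state onset detection
#'
#' Finds the time past initial relaxation by iterating: compute the
#' overall mean of the ensemble-averaged observable from the current onset
#' to the end; find the first time the ensemble average falls below that
#' mean; use it as the new onset; repeat until the onset index stops
#' changing.  The default observable is expected to decay toward its
#' steady-state value from above (e.g. the parallel gyration radius of an
#' initially extended chain).
#'
#' @param series numeric matrix (repeats x time) or vector (single
#'   repeat) of the observable on a common time grid.
#' @param max_iter iteration cap.
#' @return list with `onset` (time index), `converged`, and `steady`
#'   (FALSE when no crossing was found, in which case `onset` is the last
#'   index and the series is flagged unsteady).
#' @export
steady_state_onset <- function(series, max_iter = 100) {
  if (is.vector(series)) series <- matrix(series, nrow = 1)
  ens <- colMeans(series)
  nt <- length(ens)
  onset <- 1L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    ref <- mean(ens[onset:nt])
    cross <- which(ens <= ref)
    cross <- cross[cross >= 1]
    if (length(cross) == 0) {
      return(list(onset = nt, converged = FALSE, steady = FALSE))
    }
    new_onset <- cross[1]
    if (abs(new_onset - onset) <= 1) {
      onset <- new_onset
      converged <- TRUE
      break
    }
    onset <- new_onset
  }
  list(onset = onset, converged = converged, steady = TRUE)
}

#' Ensemble conformation summary
#'
#' Aggregates a per-frame conformation table into the ensemble-level
#' observables used for coupling sweeps.  The aspect ratio is formed from
#' ensemble-averaged squared components,
#' `beta = sqrt(<Rg_perp^2> / <Rg_par^2>)` (so an isotropic coil gives
#' `beta ~ 1` even though every instantaneous conformation is aspherical),
#' and the normalized gyration components are `r_g_par = <Rg_par> / R_rod`
#' with the closed-form rod radius and `r_g_perp = <Rg_perp> / R_coil`
#' with an empirical coil normalization (the measured `<Rg_perp>` of a
#' zero-coupling ensemble of the same length).
#'
#' @param conf per-frame table from [analyze_conformation()].
#' @param N chain length (for the rod normalization).
#' @param b mean bond length.
#' @param R_coil empirical perpendicular coil radius for the `r_g_perp`
#'   normalization (optional).
#' @return one-row data.frame with `beta`, `one_minus_beta`, `Rg_par`,
#'   `Rg_perp`, `rg_par`, `rg_perp`, `rho_par2`, `rho_perp2`, `t_par2`.
#' @export
conformation_summary <- function(conf, N, b = 0.89, R_coil = NULL) {
  beta <- sqrt(mean(conf$Rg_perp^2) / mean(conf$Rg_par^2))
  data.frame(
    beta = beta, one_minus_beta = 1 - beta,
    Rg_par = mean(conf$Rg_par), Rg_perp = mean(conf$Rg_perp),
    rg_par = mean(conf$Rg_par) / rod_gyration_radius(N, b),
    rg_perp = if (is.null(R_coil)) NA_real_ else mean(conf$Rg_perp) / R_coil,
    rho_par2 = mean(conf$rho_par2), rho_perp2 = mean(conf$rho_perp2),
    t_par2 = mean(conf$t_par2))
}

#' Per-frame conformation table for a run
#'
#' Computes the gyration decomposition, end-to-end components and tangent
#' alignment for every stored frame of a simulation run.
#'
#' @param run a `nemapoly_run` object from [run_simulation()].
#' @param nhat global director (default the cylinder axis / z).
#' @param nu,b normalization for the end-to-end components.
#' @return data.frame with one row per frame: `time`, `Rg`, `Rg_par`,
#'   `Rg_perp`, `beta`, `Re_par2`, `Re_perp2`, `rho_par2`, `rho_perp2`,
#'   `t_par2`, `bond_mean`.
#' @export
analyze_conformation <- function(run, nhat = c(0, 0, 1), nu = 3 / 5,
                                 b = 0.89) {
  frames <- run$frames
  nf <- dim(frames)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    pos <- frames[, , f]
    G <- gyration_tensor(pos)
    dg <- decompose_gyration(G, nhat)
    ee <- end_to_end_components(pos, nhat, nu, b)
    tg <- bond_tangents(pos)
    t_par2 <- mean(drop(tg %*% (nhat / sqrt(sum(nhat^2))))^2)
    out[[f]] <- data.frame(
      time = run$scalars$time[f], Rg = dg$Rg, Rg_par = dg$Rg_par,
      Rg_perp = dg$Rg_perp, beta = dg$beta, Re_par2 = ee$Re_par2,
      Re_perp2 = ee$Re_perp2, rho_par2 = ee$rho_par2,
      rho_perp2 = ee$rho_perp2, t_par2 = t_par2,
      bond_mean = run$scalars$bond_mean[f])
  }
  do.call(rbind, out)
}
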