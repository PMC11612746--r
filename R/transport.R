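# Diffusion measurement (MSD decomposition and fits) and the analytic
# transport models: single-segment partition function, Perrin prolate-
# ellipsoid drag with a confinement correction, and Kramers hopping.

#' Mean squared displacement, decomposed along a director
#'
#' Time-origin-averaged MSD of an unwrapped centre-of-mass trajectory,
#' split into the component along `nhat` (1 degree of freedom) and the
#' transverse plane (2 degrees of freedom); `total = parallel +
#' perpendicular` at every lag by construction.
#'
#' @param cm n x 3 matrix of unwrapped positions on a uniform time grid.
#' @param dt_frame time between rows.
#' @param nhat unit director.
#' @param lags integer row lags (default: ~50 log-spaced up to n/4).
#' @param origin_stride take every k-th time origin (1 = all).
#' @return data.frame with `lag`, `dt`, `msd`, `msd_par`, `msd_perp`, `n`.
#' @export
msd_components <- function(cm, dt_frame = 1, nhat = c(0, 0, 1), lags = NULL,
                           origin_stride = 1) {
  n <- nrow(cm)
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(0, log(max(n %/% 4, 2)), length.out = 50))))
  }
  lags <- lags[lags >= 1 & lags < n]
  nhat <- nhat / sqrt(sum(nhat^2))
  out <- data.frame(lag = lags, dt = lags * dt_frame, msd = NA_real_,
                    msd_par = NA_real_, msd_perp = NA_real_, n = NA_integer_)
  for (i in seq_along(lags)) {
    L <- lags[i]
    o <- seq(1, n - L, by = origin_stride)
    d <- cm[o + L, , drop = FALSE] - cm[o, , drop = FALSE]
    par2 <- drop(d %*% nhat)^2
    tot2 <- rowSums(d^2)
    out$msd[i] <- mean(tot2)
    out$msd_par[i] <- mean(par2)
    out$msd_perp[i] <- mean(tot2 - par2)
    out$n[i] <- length(o)
  }
  out
}

#' Fit diffusion coefficients from an MSD series
#'
#' Least-squares linear fit `MSD = 2 d D dt` in a lag window, with a
#' diffusive-slope guard: the local log-log slope inside the window must
#' lie in `[0.9, 1.1]`, otherwise the estimate is flagged invalid (e.g. a
#' ballistic trajectory).  Errors are estimated by refitting on 5
#' consecutive segments of the window.
#'
#' @param msd data.frame from [msd_components()].
#' @param window length-2 lag-time window `c(tmin, tmax)`.
#' @param component one of `"total"` (d = 3), `"parallel"` (d = 1),
#'   `"perpendicular"` (d = 2).
#' @param d_override optional dimensionality override (e.g. `d = 2`
#'   simulations).
#' @return list with `D`, `se`, `valid`, `slope_loglog`, `window`.
#' @export
fit_diffusion <- function(msd, window = range(msd$dt),
                          component = c("total", "parallel", "perpendicular"),
                          d_override = NULL) {
  component <- match.arg(component)
  col <- switch(component, total = "msd", parallel = "msd_par",
                perpendicular = "msd_perp")
  dfree <- if (!is.null(d_override)) d_override else
    switch(component, total = 3, parallel = 1, perpendicular = 2)
  sel <- msd$dt >= window[1] & msd$dt <= window[2] & is.finite(msd[[col]])
  if (sum(sel) < 3) stop("fewer than 3 MSD points in the fit window")
  x <- msd$dt[sel]
  y <- msd[[col]][sel]
  pos <- y > 0
  slope_ll <- if (sum(pos) >= 3) {
    unname(coef(lm(log(y[pos]) ~ log(x[pos])))[2])
  } else NA_real_
  valid <- is.finite(slope_ll) && slope_ll >= 0.9 && slope_ll <= 1.1
  D <- unname(coef(lm(y ~ 0 + x))[1]) / (2 * dfree)
  seg <- cut(seq_along(x), breaks = min(5, max(sum(sel) %/% 3, 1)),
             labels = FALSE)
  Ds <- vapply(unique(seg), function(s) {
    xi <- x[seg == s]; yi <- y[seg == s]
    if (length(xi) < 2) return(NA_real_)
    unname(coef(lm(yi ~ 0 + xi))[1]) / (2 * dfree)
  }, numeric(1))
  Ds <- Ds[is.finite(Ds)]
  list(D = D, se = if (length(Ds) > 1) sd(Ds) / sqrt(length(Ds)) else NA_real_,
       valid = valid, slope_loglog = slope_ll, window = window,
       component = component)
}

#' Anisotropic diffusion estimate from a centre-of-mass trajectory
#'
#' Convenience wrapper: MSD decomposition plus fits of `D`, `D_par`,
#' `D_perp` in a common window.  The identity `D = (D_par + 2 D_perp)/3`
#' holds within fit error for diffusive trajectories.
#'
#' @param cm unwrapped trajectory (n x 3).
#' @param dt_frame frame spacing.
#' @param nhat director.
#' @param window lag-time fit window; default `[10, tmax/4]` where tmax is
#'   the trajectory length.
#' @return list with `D`, `D_par`, `D_perp` (each a [fit_diffusion()]
#'   result), `ratio` (`D_par$D / D_perp$D`) and the `msd` table.
#' @export
diffusion_estimate <- function(cm, dt_frame = 1, nhat = c(0, 0, 1),
                               window = NULL) {
  msd <- msd_components(cm, dt_frame, nhat)
  if (is.null(window)) {
    window <- c(min(10 * dt_frame, max(msd$dt) / 10), max(msd$dt) / 4)
  }
  Dt <- fit_diffusion(msd, window, "total")
  Dp <- fit_diffusion(msd, window, "parallel")
  De <- fit_diffusion(msd, window, "perpendicular")
  list(D = Dt, D_par = Dp, D_perp = De, ratio = Dp$D / De$D, msd = msd)
}

#' Single-segment partition function
#'
#' Partition function of one bond fluctuating about the director with the
#' aligning weight `exp(kappa (1 - (t.n)^2))` (the `sin^2` approximation
#' of the harmonic angular potential), integrated over the unit sphere:
#' `Z1 = 2 pi Int_{-1}^{1} exp(kappa (1 - x^2)) dx`, evaluated by
#' adaptive quadrature (relative tolerance 1e-10).  `kappa = -k b / 2kBT`
#' is the dimensionless coupling, non-positive for aligning coupling;
#' `Z1(0) = 4 pi` (uniform sphere) and `Z1` decreases as the coupling
#' strengthens.
#'
#' @param kappa dimensionless coupling (scalar or vector), `<= 0`.
#' @return `Z1` (same length as `kappa`).
#' @export
segment_partition_function <- function(kappa) {
  if (any(kappa > 1e-12)) stop("kappa must be <= 0 (aligning coupling)")
  vapply(kappa, function(kp) {
    2 * pi * stats::integrate(function(x) exp(kp * (1 - x^2)), -1, 1,
                              rel.tol = 1e-10)$value
  }, numeric(1))
}

#' Thermodynamic tangent expectations
#'
#' Expectation of the transverse tangent fluctuations of one bond,
#' obtained by differentiating the bond free energy `-kBT ln Z1` with
#' respect to the coupling: `<2 t_perp^2> = d ln Z1 / d kappa`, and
#' `<t_par^2> = 1 - 2 <t_perp^2>`.  Two routes are provided and must
#' agree: direct quadrature of the Boltzmann average, and central
#' differences of `ln Z1`.
#'
#' @param kappa dimensionless coupling (vector allowed), `<= 0`.
#' @param method `"quadrature"` (default) or `"derivative"` (central
#'   difference of `ln Z1` with step 1e-4).
#' @return data.frame with `kappa`, `t_par2`, `t_perp2`.
#' @export
tangent_expectations <- function(kappa, method = c("quadrature",
                                                   "derivative")) {
  method <- match.arg(method)
  two_tperp2 <- vapply(kappa, function(kp) {
    if (method == "quadrature") {
      num <- stats::integrate(function(x) (1 - x^2) * exp(kp * (1 - x^2)),
                              -1, 1, rel.tol = 1e-10)$value
      den <- stats::integrate(function(x) exp(kp * (1 - x^2)), -1, 1,
                              rel.tol = 1e-10)$value
      num / den
    } else {
      h <- 1e-4
      (log(segment_partition_function(min(kp + h, 0))) -
         log(segment_partition_function(kp - h))) /
        (min(kp + h, 0) - (kp - h))
    }
  }, numeric(1))
  data.frame(kappa = kappa, t_par2 = 1 - two_tperp2,
             t_perp2 = two_tperp2 / 2)
}

# Perrin friction factors for a prolate spheroid with semi-major axis a,
# semi-minor b = beta * a, eccentricity e = sqrt(1 - beta^2):
#   f_par  = 16 pi eta a e^3 / [ (1 + e^2) L - 2 e ]
#   f_perp = 32 pi eta a e^3 / [ (3 e^2 - 1) L + 2 e ]
# with L = ln((1 + e)/(1 - e)); both reduce to Stokes 6 pi eta a as
# beta -> 1, and f_perp/f_par -> 2 as beta -> 0.
perrin_factors <- function(beta) {
  if (beta >= 1) return(c(par = 6 * pi, perp = 6 * pi))
  e2 <- (1 - beta) * (1 + beta)
  e <- sqrt(e2)
  if (e < 1e-4) { # series around the sphere to avoid cancellation
    return(c(par = 6 * pi * (1 - e2 / 5), perp = 6 * pi * (1 - e2 / 10)))
  }
  # 1 - e = beta^2 / (1 + e) avoids cancellation in the slender limit
  L <- log((1 + e) * (1 + e) / beta^2)
  c(par = 16 * pi * e^3 / ((1 + e2) * L - 2 * e),
    perp = 32 * pi * e^3 / ((3 * e2 - 1) * L + 2 * e))
}

#' Diffusivities of a prolate ellipsoid
#'
#' Perrin drag for a prolate spheroid with semi-major axis `ell` (the
#' parallel gyration radius of the polymer) and aspect ratio
#' `beta = R_g_perp / R_g_par <= 1`:
#' `D_alpha = kBT / (eta ell K_alpha)` with the dimensionless resistance
#' factors `K_alpha`.  The ratio `D_par/D_perp` depends only on `beta`,
#' equals 1 for a sphere (`beta = 1`) and rises to 2 in the thin-rod limit
#' (`beta -> 0`).
#'
#' @param beta aspect ratio in `(0, 1]`; oblate shapes (`beta > 1`) are
#'   not supported.
#' @param ell characteristic size (semi-major axis), in a.
#' @param eta fluid viscosity (kBT t0/a^3).
#' @param kBT thermal energy.
#' @return list with `D_par`, `D_perp`, `ratio`, `K_par`, `K_perp`.
#' @export
ellipsoid_diffusivities <- function(beta, ell = 1, eta = 8.6, kBT = 1) {
  if (any(beta <= 0)) stop("aspect ratio beta must be positive")
  if (any(beta > 1)) stop("oblate shapes (beta > 1) are not supported")
  K <- t(vapply(beta, perrin_factors, numeric(2)))
  D_par <- unname(kBT / (eta * ell * K[, "par"]))
  D_perp <- unname(kBT / (eta * ell * K[, "perp"]))
  list(D_par = D_par, D_perp = D_perp, ratio = D_par / D_perp,
       K_par = unname(K[, "par"]), K_perp = unname(K[, "perp"]))
}

#' Confinement (wall) correction to ellipsoid diffusivities
#'
#' Leading-order hindered-diffusion correction for a polymer of
#' zero-coupling gyration radius `Rg0` diffusing in a cylinder of radius
#' `R`: `D_alpha = D^e_alpha (1 - C_alpha Rg0 / R)`, with the fitted
#' correction parameters `C_par = 1.20`, `C_perp = 1.35`.
#'
#' @param D_par,D_perp unconfined (ellipsoid-model) diffusivities.
#' @param Rg0 gyration radius at zero coupling; must be `< R`.
#' @param R cylinder radius.
#' @param C_par,C_perp correction parameters.
#' @return list with corrected `D_par`, `D_perp`, `ratio`.
#' @export
wall_corrected_diffusivities <- function(D_par, D_perp, Rg0, R,
                                         C_par = 1.20, C_perp = 1.35) {
  if (Rg0 >= R) stop("Rg0 must be smaller than the cylinder radius")
  fp <- 1 - C_par * Rg0 / R
  fq <- 1 - C_perp * Rg0 / R
  if (fp <= 0 || fq <= 0) {
    stop("correction factor <= 0: geometry too confining for this model")
  }
  list(D_par = D_par * fp, D_perp = D_perp * fq,
       ratio = (D_par * fp) / (D_perp * fq))
}

#' Kramers hopping rate and hairpin diffusivity
#'
#' Escape rate over a barrier of height `E_b` in the overdamped limit:
#' `Gamma = sqrt(V''_a V''_b) / (2 pi zeta) * exp(-E_b / kBT)`, with the
#' well and barrier curvatures and the hairpin drag `zeta`; the hairpin
#' performs a hopping walk of step `b` along the backbone, so
#' `D_H = b^2 Gamma / 2`.
#'
#' @param E_b barrier height (kBT).
#' @param Vpp_a curvature of the well (kBT).
#' @param Vpp_b curvature of the barrier (kBT).
#' @param zeta drag coefficient of the hairpin (kBT t0 / a^2).
#' @param b hop length (mean bond length, a).
#' @param kBT thermal energy.
#' @return list with `Gamma` and `D_H`.
#' @export
kramers_hopping <- function(E_b, Vpp_a, Vpp_b, zeta, b = 0.89, kBT = 1) {
  if (any(Vpp_a <= 0) || any(Vpp_b <= 0)) stop("curvatures must be positive")
  if (any(zeta <= 0)) stop("drag zeta must be positive")
  Gamma <- sqrt(Vpp_a * Vpp_b) / (2 * pi * zeta) * exp(-E_b / kBT)
  list(Gamma = Gamma, D_H = b^2 * Gamma / 2)
}

#' Kramers estimate from the coupling constant
#'
#' Convenience wrapper with the plug-in estimates for a hairpin hop: both
#' the barrier and the curvatures scale with the coupling (`E_b = c1 k`,
#' `V'' = c2 k`) and the drag follows from the uncoupled centre-of-mass
#' diffusivity by Einstein's relation (`zeta = kBT / D0`).  Prefactors are
#' order-of-magnitude calibrations, exposed as arguments.
#'
#' @param k coupling constant (kBT).
#' @param D0 uncoupled polymer diffusion coefficient (a^2/t0).
#' @param b mean bond length.
#' @param c1,c2 dimensionless prefactors of the barrier and curvature
#'   estimates.
#' @param kBT thermal energy.
#' @return list with `Gamma`, `D_H`, `E_b`, `zeta`.
#' @export
kramers_from_coupling <- function(k, D0 = 300e-5, b = 0.89, c1 = 1, c2 = 1,
                                  kBT = 1) {
  zeta <- kBT / D0
  res <- kramers_hopping(c1 * k, c2 * k, c2 * k, zeta, b, kBT)
  c(res, list(E_b = c1 * k, zeta = zeta))
}
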