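# Independent oracles and fixture builders used across the test files.

# Normalizing quadrature for the orientation-collision density
# p(x) propto exp(a x^2) on x = u.n in [-1, 1].
ms_moment_quad <- function(a, moment = 2) {
  num <- integrate(function(x) x^moment * exp(a * x^2), -1, 1,
                   rel.tol = 1e-10)$value
  den <- integrate(function(x) exp(a * x^2), -1, 1, rel.tol = 1e-10)$value
  num / den
}

ms_cdf_quad <- function(q, a) {
  den <- integrate(function(x) exp(a * x^2), -1, 1, rel.tol = 1e-10)$value
  vapply(q, function(qi) {
    integrate(function(x) exp(a * x^2), -1, qi, rel.tol = 1e-10)$value / den
  }, numeric(1))
}

# Self-consistent mean-field fixed point: S = (3/2) <x^2>_a - 1/2 with
# a = (3/2) U S (3D).
ms_fixed_point <- function(U, S0 = 0.8, iter = 400) {
  S <- S0
  for (i in seq_len(iter)) S <- 1.5 * ms_moment_quad(1.5 * U * S) - 0.5
  S
}

# Perrin friction via the classical resistance integrals:
# f_i = 16 pi eta / (chi + a_i^2 alpha_i), with
# chi = Int_0^inf ds / Delta, alpha_i = Int_0^inf ds / ((a_i^2 + s) Delta),
# Delta = sqrt((a^2+s)(b^2+s)^2) for a prolate spheroid (b = c).
perrin_ratio_integral <- function(beta, amaj = 1) {
  bmin <- beta * amaj
  Delta <- function(s) sqrt((amaj^2 + s)) * (bmin^2 + s)
  chi <- integrate(function(s) 1 / Delta(s), 0, Inf, rel.tol = 1e-10)$value
  alpha_a <- integrate(function(s) 1 / ((amaj^2 + s) * Delta(s)), 0, Inf,
                       rel.tol = 1e-10)$value
  alpha_b <- integrate(function(s) 1 / ((bmin^2 + s) * Delta(s)), 0, Inf,
                       rel.tol = 1e-10)$value
  f_par <- 16 * pi / (chi + amaj^2 * alpha_a)
  f_perp <- 16 * pi / (chi + bmin^2 * alpha_b)
  f_perp / f_par # = D_par / D_perp
}

# Freely-jointed random walk conformation (fixed seed upstream).
rand_fjc <- function(N, b = 0.89) {
  z <- runif(N - 1, -1, 1)
  ph <- runif(N - 1, 0, 2 * pi)
  st <- sqrt(1 - z^2)
  steps <- b * cbind(st * cos(ph), st * sin(ph), z)
  rbind(0, apply(steps, 2, cumsum))
}

# U-turn with arms of `narm` bonds along +/- nhat (z): the chain runs up,
# turns at a single apex bead, and runs straight back down with a small
# transverse offset.  2*narm + 1 beads, apex at index narm + 1.
make_uturn <- function(narm = 6, b = 0.89) {
  up <- cbind(0, 0, b * (0:narm))
  down <- cbind(0.3, 0, b * ((narm - 1):0))
  rbind(up, down)
}

# Overdamped Langevin simulation in a tilted-cosine double well; returns
# the empirical escape rate out of a well (mean first-passage based).
langevin_escape_rate <- function(Eb, zeta = 1, kBT = 1, dt = 2e-3,
                                 nsteps = 4e5) {
  # V(x) = (Eb/2)(1 - cos(2 pi x)): barrier Eb between minima at integers,
  # V''(min) = V''(max) = 2 pi^2 Eb
  x <- 0
  crossings <- 0
  sd_step <- sqrt(2 * kBT * dt / zeta)
  drift <- -pi * Eb * dt / zeta
  noise <- rnorm(nsteps)
  base <- 0
  for (i in seq_len(nsteps)) {
    x <- x + drift * sin(2 * pi * (x - base)) + sd_step * noise[i]
    if (abs(x - base) >= 1) {
      crossings <- crossings + 1
      base <- round(x)
    }
  }
  crossings / (nsteps * dt)
}
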