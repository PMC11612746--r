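# MSD decomposition and fits, segment partition function, Perrin ellipsoid
# drag, wall correction, Kramers hopping.

test_that("MSD decomposition: identity, ballistic flag, Brownian recovery", {
  # total = parallel + perpendicular at all lags
  set.seed(40)
  cm <- apply(matrix(rnorm(3 * 2000, sd = 0.05), ncol = 3), 2, cumsum)
  msd <- msd_components(cm, dt_frame = 1)
  expect_lt(max(abs(msd$msd - msd$msd_par - msd$msd_perp)), 1e-12)
  expect_true(all(msd$lag >= 1))
  # ballistic trajectory: the diffusive guard flags the fit invalid
  t <- seq_len(500)
  ball <- cbind(0.1 * t, 0, 0)
  msd_b <- msd_components(ball, dt_frame = 1)
  fit_b <- fit_diffusion(msd_b, window = c(5, 100), component = "total")
  expect_false(fit_b$valid)
  expect_gt(fit_b$slope_loglog, 1.8)
  # synthetic anisotropic Brownian motion D_par = 2 D_perp = 0.002
  set.seed(41)
  n <- 1e4
  cm2 <- cbind(cumsum(rnorm(n, sd = sqrt(2 * 0.001))),
               cumsum(rnorm(n, sd = sqrt(2 * 0.001))),
               cumsum(rnorm(n, sd = sqrt(2 * 0.002))))
  msd2 <- msd_components(cm2, dt_frame = 1)
  fpar <- fit_diffusion(msd2, window = c(1, 100), component = "parallel")
  fperp <- fit_diffusion(msd2, window = c(1, 100), component = "perpendicular")
  expect_true(fpar$valid)
  expect_equal(fpar$D, 0.002, tolerance = 0.05)
  expect_equal(fperp$D, 0.001, tolerance = 0.05)
})

test_that("exact linear MSD returns the imposed coefficient", {
  dt <- 1:50
  msd <- data.frame(lag = dt, dt = dt, msd = 2 * 3 * 1e-3 * dt,
                    msd_par = 2 * 1 * 1e-3 * dt,
                    msd_perp = 2 * 2 * 1e-3 * dt, n = 100)
  expect_equal(fit_diffusion(msd, c(1, 50), "total")$D, 1e-3, tolerance = 1e-10)
  expect_equal(fit_diffusion(msd, c(1, 50), "parallel")$D, 1e-3,
               tolerance = 1e-10)
  # D = (D_par + 2 D_perp) / 3 identity on consistent components
  est <- list(D = fit_diffusion(msd, c(1, 50), "total")$D,
              Dp = fit_diffusion(msd, c(1, 50), "parallel")$D,
              De = fit_diffusion(msd, c(1, 50), "perpendicular")$D)
  expect_equal(est$D, (est$Dp + 2 * est$De) / 3, tolerance = 1e-10)
})

test_that("segment partition function: uniform limit, MC check, monotonicity", {
  expect_equal(segment_partition_function(0), 4 * pi, tolerance = 1e-10)
  expect_error(segment_partition_function(0.5), "kappa")
  # Monte-Carlo sphere average oracle at kappa = -3
  set.seed(42)
  nmc <- 1e6
  x <- runif(nmc, -1, 1)
  mc <- 4 * pi * mean(exp(-3 * (1 - x^2)))
  se <- 4 * pi * sd(exp(-3 * (1 - x^2))) / sqrt(nmc)
  expect_lt(abs(segment_partition_function(-3) - mc), 3 * se)
  # strictly decreasing with coupling strength
  z <- segment_partition_function(-(0:10))
  expect_true(all(diff(z) < 0))
  # closed form via the imaginary error function:
  # Z1(kappa) = 2 pi e^kappa sqrt(pi / -kappa) erfi(sqrt(-kappa))
  closed <- 2 * pi * exp(-4) * sqrt(pi / 4) * pracma::erfi(2)
  expect_equal(segment_partition_function(-4), closed, tolerance = 1e-8)
})

test_that("tangent expectations: limits, identity, dual-route agreement", {
  te0 <- tangent_expectations(0)
  expect_equal(te0$t_perp2, 1 / 3, tolerance = 1e-8) # isotropic coil value
  # strong coupling freezes alignment
  teS <- tangent_expectations(-50)
  expect_gt(teS$t_par2, 0.97)
  expect_lt(teS$t_perp2, 0.02)
  # identity at every kappa
  kg <- -seq(0, 10, by = 0.5)
  te <- tangent_expectations(kg)
  expect_lt(max(abs(te$t_par2 + 2 * te$t_perp2 - 1)), 1e-8)
  # quadrature and free-energy-derivative routes agree
  ted <- tangent_expectations(kg, method = "derivative")
  expect_equal(te$t_perp2, ted$t_perp2, tolerance = 1e-6)
})

test_that("ellipsoid diffusivities: sphere and rod limits, quadrature check", {
  sph <- ellipsoid_diffusivities(1, ell = 2, eta = 8.6)
  expect_equal(sph$ratio, 1)
  # Stokes drag recovered: D = kBT / (6 pi eta a)
  expect_equal(sph$D_par, 1 / (6 * pi * 8.6 * 2), tolerance = 1e-10)
  # thin-rod limit: the ratio converges (logarithmically slowly) to 2 from
  # below; the limit is recovered by extrapolation in 1/ln(1/beta)
  betas <- 10^-(4:12)
  rr <- ellipsoid_diffusivities(betas)$ratio
  expect_true(all(diff(rr) > 0))
  expect_true(all(rr < 2))
  expect_gt(ellipsoid_diffusivities(1e-12)$ratio, 1.9)
  x <- 1 / log(1 / betas)
  lim <- unname(coef(lm(rr ~ x + I(x^2)))[1])
  expect_equal(lim, 2, tolerance = 1e-3)
  # beta = 0.5 against the independent Perrin resistance integrals
  expect_equal(ellipsoid_diffusivities(0.5)$ratio, perrin_ratio_integral(0.5),
               tolerance = 1e-6)
  # ratio bounded in [1, 2] and monotone decreasing in beta
  bs <- seq(0.05, 1, by = 0.05)
  rs <- ellipsoid_diffusivities(bs)$ratio
  expect_true(all(rs >= 1 - 1e-12 & rs <= 2 + 1e-12))
  expect_true(all(diff(rs) < 0))
  expect_error(ellipsoid_diffusivities(1.2), "oblate")
})

test_that("wall correction: trivial, monotone and guarded", {
  e <- ellipsoid_diffusivities(0.6, ell = 3, eta = 8.6)
  w0 <- wall_corrected_diffusivities(e$D_par, e$D_perp, Rg0 = 2, R = 10,
                                     C_par = 0, C_perp = 0)
  expect_equal(w0$D_par, e$D_par)
  # correction strictly decreasing in C and in Rg0/R
  w1 <- wall_corrected_diffusivities(e$D_par, e$D_perp, 2, 10)
  w2 <- wall_corrected_diffusivities(e$D_par, e$D_perp, 3, 10)
  expect_lt(w1$D_par, e$D_par)
  expect_lt(w2$D_par, w1$D_par)
  # the reference corrections (C_perp > C_par) raise the ratio
  expect_gt(w1$ratio, e$ratio)
  expect_error(wall_corrected_diffusivities(e$D_par, e$D_perp, 11, 10),
               "smaller")
  expect_error(wall_corrected_diffusivities(e$D_par, e$D_perp, 9.99, 10),
               "confining")
})

test_that("Kramers rate: prefactor limit, exponential law, Langevin oracle", {
  k0 <- kramers_hopping(0, 4, 4, 2)
  expect_equal(k0$Gamma, 4 / (2 * pi * 2))
  # ln D_H linear in E_b with slope -1/kBT
  Eb <- seq(1, 6, by = 1)
  DH <- vapply(Eb, function(e) kramers_hopping(e, 4, 4, 2)$D_H, numeric(1))
  slopes <- diff(log(DH)) / diff(Eb)
  expect_equal(unname(slopes), rep(-1, length(slopes)), tolerance = 1e-10)
  expect_error(kramers_hopping(1, -1, 4, 2), "curvatures")
  # overdamped double-well escape oracle in the high-barrier regime:
  # V = (Eb/2)(1 - cos(2 pi x)), V'' = 2 pi^2 Eb at both extrema; the
  # simulated escape rate (both directions) matches 2 Gamma within 20%
  set.seed(43)
  Eb <- 4.5
  rate <- langevin_escape_rate(Eb, zeta = 1, dt = 1e-3, nsteps = 8e5)
  pred <- 2 * kramers_hopping(Eb, 2 * pi^2 * Eb, 2 * pi^2 * Eb, 1)$Gamma
  expect_equal(rate, pred, tolerance = 0.2)
  # convenience wrapper wiring
  kw <- kramers_from_coupling(10, D0 = 300e-5, c1 = 0.5, c2 = 1)
  expect_equal(kw$E_b, 5)
  expect_equal(kw$zeta, 1 / 300e-5)
  expect_equal(kw$D_H, 0.89^2 / 2 * sqrt(100) / (2 * pi * kw$zeta) * exp(-5),
               tolerance = 1e-10)
})
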