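# The N-MPCD solvent operations: streaming, binning, velocity collision,
# cell order parameters, Maier-Saupe orientation sampling, Jeffery coupling
# and backflow compensation.

test_that("streaming is exactly ballistic", {
  expect_equal(stream_particles(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3), 0.1),
               matrix(c(0.1, 0, 0), 1, 3))
  set.seed(1)
  r <- matrix(runif(3000, 0, 10), ncol = 3)
  v <- matrix(rnorm(3000), ncol = 3)
  expect_equal(stream_particles(r, v, 0.07), r + 0.07 * v, tolerance = 0)
  expect_equal(stream_particles(r, 0 * v, 0.1), r)
})

test_that("grid-shifted binning matches the brute-force floor rule", {
  expect_equal(drop(bin_with_grid_shift(matrix(c(0.4, 0.4, 0.4), 1, 3))),
               c(0L, 0L, 0L))
  expect_equal(drop(bin_with_grid_shift(matrix(c(0.4, 0, 0), 1, 3),
                                        shift = c(0.2, 0, 0)))[1],
               as.integer(floor(0.4 + 0.2)))
  set.seed(2)
  r <- matrix(runif(600, 0, 8), ncol = 3)
  sh <- c(-0.3, 0.45, 0.1)
  idx <- bin_with_grid_shift(r, sh, box = c(8, 8, 8))
  brute <- floor((sweep(r, 2, sh, "+")) %% 8)
  expect_equal(idx, matrix(as.integer(brute), ncol = 3))
  # every particle in exactly one cell; populations sum to the count
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  expect_equal(sum(table(key)), nrow(r))
})

test_that("velocity collision conserves momentum exactly and thermalizes", {
  set.seed(3)
  n <- 12
  pos <- matrix(runif(3 * n), n, 3)
  v <- matrix(rnorm(3 * n, sd = 2), n, 3)
  mass <- c(rep(1, n - 2), 10, 10) # two heavy monomers participate
  vn <- andersen_velocity_collision(v, mass, kBT = 1, pos = pos,
                                    angular = TRUE)
  expect_lt(max(abs(colSums(mass * vn) - colSums(mass * v))), 1e-10)
  # angular momentum about the cell COM is restored too
  com <- colSums(pos * mass) / sum(mass)
  dr <- sweep(pos, 2, com, "-")
  angmom <- function(vv) colSums(mass * cbind(
    dr[, 2] * vv[, 3] - dr[, 3] * vv[, 2],
    dr[, 3] * vv[, 1] - dr[, 1] * vv[, 3],
    dr[, 1] * vv[, 2] - dr[, 2] * vv[, 1]))
  expect_lt(max(abs(angmom(vn) - angmom(v))), 1e-9)
  # single member: xi - <xi> = 0, velocity unchanged
  expect_equal(andersen_velocity_collision(v[1, , drop = FALSE], 1),
               v[1, , drop = FALSE])
  # relative velocities are Maxwell-Boltzmann at kBT
  set.seed(4)
  nbig <- 1e5
  vb <- matrix(rnorm(3 * nbig, sd = 3), nbig, 3)
  vbn <- andersen_velocity_collision(vb, 1, kBT = 1, angular = FALSE)
  rel <- vbn[, 1] - mean(vbn[, 1])
  expect_lt(abs(var(rel) - 1), 0.01)
  ks <- suppressWarnings(ks.test(rel, "pnorm", 0, sd(rel)))
  expect_gt(ks$p.value, 0.01)
})

test_that("cell order parameters recover aligned, mixed-sign and isotropic cells", {
  uz <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  op <- cell_order_parameters(uz)
  expect_equal(op$S, 1)
  expect_equal(abs(op$director[3]), 1)
  # head-tail symmetry: u and -u mixed give the same result
  umix <- uz * rep(c(1, -1), 5)
  op2 <- cell_order_parameters(umix)
  expect_equal(op2$S, 1)
  expect_equal(abs(op2$director[3]), 1)
  # isotropic orientations: small finite-sample S
  set.seed(5)
  z <- runif(1e4, -1, 1); ph <- runif(1e4, 0, 2 * pi); st <- sqrt(1 - z^2)
  uiso <- cbind(st * cos(ph), st * sin(ph), z)
  expect_lt(cell_order_parameters(uiso)$S, 0.05)
})

test_that("Maier-Saupe sampler matches quadrature and the isotropic limit", {
  u0 <- sample_maier_saupe(2e5, 0, seed = 11)
  # uniform on the sphere: x = u.n ~ Uniform(-1, 1)
  ks <- suppressWarnings(ks.test(u0[, 3], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  expect_lt(max(abs(sqrt(rowSums(u0^2)) - 1)), 1e-12)
  # aligned regime: CDF of u.n against quadrature of exp(a x^2)
  a <- 5
  u <- sample_maier_saupe(5e5, a, seed = 12)
  qs <- seq(-0.95, 0.95, by = 0.05)
  emp <- ecdf(u[, 3])(qs)
  expect_lt(max(abs(emp - ms_cdf_quad(qs, a))), 0.005)
  # nematic symmetry: u and -u equiprobable
  expect_lt(abs(mean(u[, 3] > 0) - 0.5), 0.005)
  # moment against quadrature
  expect_equal(mean(u[, 3]^2), ms_moment_quad(a), tolerance = 0.005)
})

test_that("velocity-gradient fit recovers an imposed linear flow", {
  set.seed(6)
  pos <- matrix(runif(60), 20, 3)
  G <- matrix(c(0, 0.5, 0, 0.2, 0, 0, 0, 0, -0.1), 3, 3, byrow = TRUE)
  vel <- t(G %*% t(pos))
  expect_equal(velocity_gradient_fit(pos, vel), G, tolerance = 1e-10)
  expect_error(velocity_gradient_fit(pos[1:3, ], vel[1:3, ]), "at least")
})

test_that("Jeffery update: invariance at zero gradient, co-rotation, shear alignment", {
  set.seed(7)
  u <- sample_maier_saupe(50, 2, seed = 13)
  expect_equal(jeffery_orientation_update(u, matrix(0, 3, 3), 2, 0.5, 0.1), u)
  # pure rotation about z at rate w: u co-rotates with angular velocity
  # alpha * w (lambda plays no role)
  w <- 0.4; alpha <- 0.5; dt <- 1e-3
  G <- matrix(c(0, -w, 0, w, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  u0 <- matrix(c(1, 0, 0), 1, 3)
  u1 <- jeffery_orientation_update(u0, G, lambda = 2, alpha = alpha, dt = dt)
  ang <- alpha * w * dt
  expect_equal(drop(u1), c(cos(ang), sin(ang), 0), tolerance = 1e-6)
  # simple shear dvx/dy = g: stationary angle from the independent
  # angular-velocity root; for tumbling parameter lambda, cos(2 theta*) = 1/lambda
  g <- 1
  Gs <- matrix(c(0, g, 0, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  thdot <- function(th) {
    u <- matrix(c(cos(th), sin(th), 0), 1, 3)
    un <- jeffery_orientation_update(u, Gs, lambda = 2, alpha = 1, dt = 1e-5)
    (atan2(un[2], un[1]) - th) / 1e-5
  }
  th_star <- uniroot(thdot, c(0.05, pi / 4))$root
  expect_equal(cos(2 * th_star), 1 / 2, tolerance = 1e-3)
  # iterating the update from a generic angle converges to the same angle
  u <- matrix(c(cos(1.2), sin(1.2), 0), 1, 3)
  for (i in 1:4000) u <- jeffery_orientation_update(u, Gs, 2, 1, 5e-3)
  expect_equal(atan2(u[2], u[1]), th_star, tolerance = 1e-3)
})

test_that("backflow compensation returns the director angular impulse to the flow", {
  set.seed(8)
  n <- 20
  pos <- matrix(runif(3 * n), n, 3)
  u_old <- sample_maier_saupe(n, 3, seed = 14)
  u_new <- sample_maier_saupe(n, 3, seed = 15)
  dv <- backflow_compensation(pos, 1, u_old, u_old, gamma_R = 0.01)
  expect_equal(dv, matrix(0, n, 3)) # no orientation change, no correction
  dv <- backflow_compensation(pos, 1, u_old, u_new, gamma_R = 0.01)
  # linear momentum unchanged
  expect_lt(max(abs(colSums(dv))), 1e-10)
  # angular impulse of the correction balances gamma_R * sum(dtheta)
  com <- colMeans(pos)
  dr <- sweep(pos, 2, com, "-")
  Lcorr <- colSums(cbind(dr[, 2] * dv[, 3] - dr[, 3] * dv[, 2],
                         dr[, 3] * dv[, 1] - dr[, 1] * dv[, 3],
                         dr[, 1] * dv[, 2] - dr[, 2] * dv[, 1]))
  dL <- c(0, 0, 0)
  for (i in 1:n) {
    a <- u_old[i, ]; b <- u_new[i, ]
    if (sum(a * b) < 0) b <- -b
    cx <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    sn <- sqrt(sum(cx^2))
    if (sn > 0) dL <- dL + 0.01 * atan2(sn, sum(a * b)) * cx / sn
  }
  expect_equal(Lcorr, -dL, tolerance = 1e-10)
  # with the reference gamma_R the correction is a tiny fraction of the
  # thermal velocity
  expect_lt(sqrt(mean(dv^2)), 0.01 * 1)
})
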