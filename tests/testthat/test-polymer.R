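# FENE / WCA / coupling potentials and the velocity-Verlet integrator.

test_that("FENE closed form, limits and divergence guard", {
  # frozen value: V(0.5; 120, 1) = -60 ln(0.75)
  f <- fene_energy_force(0.5, 120, 1)
  expect_equal(f$energy, -60 * log(0.75), tolerance = 1e-12)
  expect_equal(f$energy, 17.2613, tolerance = 1e-4)
  expect_equal(f$force, -120 * 0.5 / 0.75)
  # r -> 0: V -> 0 and force -> 0
  f0 <- fene_energy_force(1e-8, 120, 1)
  expect_lt(abs(f0$energy), 1e-12)
  expect_lt(abs(f0$force), 1e-5)
  expect_error(fene_energy_force(1.0, 120, 1), "divergence")
  expect_error(fene_energy_force(-0.1, 120, 1), "positive")
  # force is the derivative of the energy (central difference oracle)
  h <- 1e-7
  num <- -(fene_energy_force(0.7 + h)$energy -
             fene_energy_force(0.7 - h)$energy) / (2 * h)
  expect_equal(fene_energy_force(0.7)$force, num, tolerance = 1e-5)
})

test_that("WCA cutoff, contact value and closed form", {
  rc <- 2^(1 / 6)
  w <- wca_energy_force(rc, 1, 1)
  expect_equal(w$energy, 0)
  expect_equal(w$force, 0)
  expect_equal(wca_energy_force(rc + 1e-9)$energy, 0)
  expect_equal(wca_energy_force(1, 1, 1)$energy, 1) # 4(1 - 1) + eps
  w9 <- wca_energy_force(0.9, 1, 1)
  s6 <- (1 / 0.9)^6
  expect_equal(w9$energy, 4 * (s6^2 - s6) + 1, tolerance = 1e-12)
  h <- 1e-7
  num <- -(wca_energy_force(0.95 + h)$energy -
             wca_energy_force(0.95 - h)$energy) / (2 * h)
  expect_equal(wca_energy_force(0.95)$force, num, tolerance = 1e-4)
  expect_error(wca_energy_force(0), "positive")
})

test_that("coupling potential uses the acute angle and balances forces", {
  n <- c(0, 0, 1)
  # parallel and antiparallel bonds are both unpenalized (hairpin arms)
  par <- npc_energy_force(c(0, 0, 1), c(0, 0, 0), n, 20)
  anti <- npc_energy_force(c(0, 0, 0), c(0, 0, 1), n, 20)
  expect_equal(par$energy, 0)
  expect_equal(anti$energy, 0)
  expect_equal(par$force_j, c(0, 0, 0))
  # perpendicular bond: V = k (pi/2)^2 / 2, frozen value 24.674 at k = 20
  perp <- npc_energy_force(c(1, 0, 0), c(0, 0, 0), n, 20)
  expect_equal(perp$energy, 20 * (pi / 2)^2 / 2, tolerance = 1e-12)
  expect_equal(perp$energy, 24.674, tolerance = 1e-3)
  expect_equal(perp$torque, 20 * pi / 2)
  # Newton's third law and zero net force
  oblique <- npc_energy_force(c(0.6, 0.2, 0.9), c(0, 0, 0.1), n, 12)
  expect_equal(oblique$force_j + oblique$force_l, c(0, 0, 0))
  # force agrees with a numerical gradient of the energy in theta
  rj <- c(sin(0.7), 0, cos(0.7))
  res <- npc_energy_force(rj, c(0, 0, 0), n, 12)
  h <- 1e-6
  e1 <- npc_energy_force(c(sin(0.7 + h), 0, cos(0.7 + h)), c(0, 0, 0), n, 12)$energy
  e0 <- npc_energy_force(c(sin(0.7 - h), 0, cos(0.7 - h)), c(0, 0, 0), n, 12)$energy
  # tangential force magnitude = dV/dtheta / r = k theta (unit bond)
  expect_equal(sqrt(sum(res$force_j^2)), (e1 - e0) / (2 * h), tolerance = 1e-4)
  expect_error(npc_energy_force(c(0, 0, 0), c(0, 0, 0), n, 12), "zero-length")
})

test_that("velocity Verlet: ballistic exactness, energy drift, reversibility", {
  # zero forces: exact ballistic motion
  pos <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  vel <- matrix(c(0.3, 0, 0, -0.1, 0.2, 0), 2, 3, byrow = TRUE)
  out <- md_verlet(pos, vel, 1, function(p) matrix(0, 2, 3), 0.01, 100)
  expect_equal(out$pos, pos + vel * 1, tolerance = 1e-12)
  # harmonic dimer energy drift at dt_MD = 0.002
  kh <- 100
  hforce <- function(p) {
    d <- p[2, ] - p[1, ]
    r <- sqrt(sum(d^2))
    f <- kh * (r - 1) * d / r
    rbind(f, -f)
  }
  henergy <- function(p, v) {
    d <- p[2, ] - p[1, ]
    0.5 * kh * (sqrt(sum(d^2)) - 1)^2 + 0.5 * sum(v^2)
  }
  p0 <- matrix(c(0, 0, 0, 1.2, 0, 0), 2, 3, byrow = TRUE)
  v0 <- matrix(c(0, 0.1, 0, 0, -0.1, 0), 2, 3, byrow = TRUE)
  e0 <- henergy(p0, v0)
  out <- md_verlet(p0, v0, 1, hforce, 0.002, 3e4)
  expect_lt(abs(henergy(out$pos, out$vel) - e0) / e0, 1e-4)
  # time reversal returns the initial state
  fwd <- md_verlet(p0, v0, 1, hforce, 0.002, 1000)
  back <- md_verlet(fwd$pos, -fwd$vel, 1, hforce, 0.002, 1000)
  expect_equal(back$pos, p0, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(-back$vel, v0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("chain forces obey Newton's third law and report energies", {
  set.seed(10)
  pos <- rand_fjc(8, 0.9)
  cf <- chain_forces(pos, k = 5)
  expect_lt(max(abs(colSums(cf$forces))), 1e-9)
  expect_gte(cf$e_fene, 0)
  expect_gte(cf$e_wca, 0)
  expect_gte(cf$e_npc, 0)
})
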