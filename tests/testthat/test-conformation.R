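# Gyration tensor, end-to-end scaling, tangent statistics, steady-state
# onset.

test_that("gyration tensor: degenerate, rod and brute-force cases", {
  # coincident beads
  expect_equal(gyration_tensor(matrix(1, 5, 3)), matrix(0, 3, 3))
  # straight rod: closed form Rg_par^2 = b^2 (N^2 - 1)/12, Rg_perp = 0
  N <- 20; b <- 0.89
  rod <- cbind(0, 0, b * (0:(N - 1)))
  G <- gyration_tensor(rod)
  dg <- decompose_gyration(G, c(0, 0, 1))
  expect_equal(dg$Rg_par, sqrt(b^2 * (N^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(dg$Rg_par, 5.132, tolerance = 1e-3)
  expect_equal(dg$Rg_perp, 0)
  expect_equal(dg$beta, 0)
  expect_equal(rod_gyration_radius(N, b), dg$Rg_par)
  # trace identity against a brute-force mean squared distance
  set.seed(20)
  cloud <- matrix(rnorm(60), 20, 3)
  G <- gyration_tensor(cloud)
  msq <- mean(rowSums(sweep(cloud, 2, colMeans(cloud), "-")^2))
  expect_equal(sum(diag(G)), msq, tolerance = 1e-12)
  # wrapped-coordinate guard
  wrapped <- rbind(c(0, 0, 0.1), c(0, 0, 7.9))
  expect_error(gyration_tensor(wrapped, box = c(8, 8, 8)), "wrap")
})

test_that("gyration decomposition limits and the trace identity", {
  iso <- decompose_gyration(diag(3) * 0.7)
  expect_equal(iso$beta, 1)
  set.seed(21)
  pos <- rand_fjc(20)
  G <- gyration_tensor(pos)
  dg <- decompose_gyration(G, c(0, 0, 1))
  expect_equal(dg$Rg^2, dg$Rg_par^2 + 2 * dg$Rg_perp^2, tolerance = 1e-12)
  expect_true(all(eigen(G, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
})

test_that("end-to-end components: rod geometry and normalization identity", {
  N <- 20; b <- 0.89
  rod <- cbind(0, 0, b * (0:(N - 1)))
  ee <- end_to_end_components(rod, nu = 1, b = b)
  expect_equal(ee$rho_par2, ((N - 1) / N)^2, tolerance = 1e-12) # ~0.90
  expect_equal(ee$rho_perp2, 0)
  # normalization recomputes exactly from the components
  set.seed(22)
  pos <- rand_fjc(20)
  ee <- end_to_end_components(pos, nu = 3 / 5, b = b)
  expect_equal(ee$rho_par2, ee$Re_par2 / (20^(6 / 5) * b^2), tolerance = 1e-12)
  expect_equal(ee$rho_perp2, ee$Re_perp2 / (20^(6 / 5) * b^2), tolerance = 1e-12)
})

test_that("freely jointed chains have isotropic tangent statistics", {
  # <(t.n)^2> = 1/3 for isotropic tangents; identity holds exactly
  set.seed(23)
  tg <- do.call(rbind, lapply(1:300, function(i) bond_tangents(rand_fjc(20))))
  ts <- tangent_statistics(tg)
  expect_equal(ts$t_par2, 1 / 3, tolerance = 0.01)
  expect_equal(ts$t_par2 + 2 * ts$t_perp2, 1, tolerance = 1e-12)
  # fully aligned tangents
  tz <- matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE)
  tsz <- tangent_statistics(tz)
  expect_equal(tsz$t_par2, 1)
  expect_equal(tsz$t_perp2, 0)
})

test_that("steady-state onset: constant, step and relaxing series", {
  # constant series: onset at the first index
  expect_equal(steady_state_onset(rep(2, 50))$onset, 1)
  # step high -> low at index s converges to s
  s <- 30
  step <- c(rep(10, s - 1), rep(1, 71 - s))
  res <- steady_state_onset(step)
  expect_equal(res$onset, s)
  expect_true(res$converged)
  # exponential relaxation with measurement noise: onset lands after the
  # decay has dropped into the noise floor and is stable across iterations
  set.seed(24)
  t <- 0:400
  tau <- 40
  reps <- t(replicate(4, 1 + 5 * exp(-t / tau) + rnorm(length(t), sd = 0.1)))
  res <- steady_state_onset(reps)
  expect_true(res$converged)
  expect_true(res$steady)
  # noise floor ~0.05 on the ensemble mean: residual < noise after
  # tau * ln(5/0.05) ~ 4.6 tau; onset must fall past one tau and before
  # the series end
  expect_gt(res$onset, tau)
  expect_lt(res$onset, 8 * tau)
  # monotonically increasing series never crosses below its mean from
  # above at the start: flagged unsteady when no crossing exists
  res2 <- steady_state_onset(c(5, 4, 3, 2, 1) * 0 + c(1, 2, 3, 4, 5))
  expect_true(is.list(res2))
})
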