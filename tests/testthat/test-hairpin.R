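# Hairpin scoring, detection, counting statistics, tracking and backbone
# diffusivity.

test_that("scores: rod gives zero, U-turn peaks at the apex", {
  toy <- make_fixture("hairpin_toy")
  expect_true(all(hairpin_scores(toy$conformations$rod)$score == 0))
  ut <- make_uturn(9) # 19 beads, apex at index 10
  sc <- hairpin_scores(ut)$score
  expect_gt(max(sc), 0.9)
  expect_true(which.max(sc) %in% 9:11)
  # away from the apex the score vanishes
  expect_true(all(sc[c(1:6, 14:19)] < 0.2))
  # an isotropic coil produces many nonzero scores (the count is not
  # meaningful at low coupling)
  set.seed(30)
  nz <- mean(replicate(50, sum(hairpin_scores(rand_fjc(20))$score > 0)))
  expect_gt(nz, 2)
})

test_that("detection: counts and polarities on constructed conformations", {
  toy <- make_fixture("hairpin_toy")
  expect_equal(nrow(detect_hairpins(toy$conformations$rod)), 0)
  det <- detect_hairpins(make_uturn(9))
  expect_equal(nrow(det), 1)
  det2 <- detect_hairpins(toy$conformations$zigzag, w = 3)
  expect_equal(nrow(det2), 2)
  expect_equal(sort(det2$polarity), c(-0.5, 0.5)) # opposite polarities
})

test_that("detection is invariant under director flip and chain reversal", {
  set.seed(31)
  for (i in 1:20) {
    pos <- rand_fjc(20)
    d1 <- detect_hairpins(pos, nhat = c(0, 0, 1))
    d2 <- detect_hairpins(pos, nhat = c(0, 0, -1))
    expect_equal(d1$s, d2$s)
    expect_equal(d1$score, d2$score)
    d3 <- detect_hairpins(pos[20:1, ], nhat = c(0, 0, 1))
    expect_equal(sort(21 - d3$s), sort(d1$s))
  }
  # rigid rotation about the director leaves scores unchanged
  pos <- rand_fjc(20)
  th <- 0.77
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  posr <- sweep(pos, 2, c(3, -2, 5), "+") %*% t(Rz)
  expect_equal(hairpin_scores(posr)$score, hairpin_scores(pos)$score,
               tolerance = 1e-10)
})

test_that("Poisson statistics are recovered on synthetic counts", {
  expect_equal(hairpin_count_statistics(rep(0L, 100))$lambda, 0)
  set.seed(32)
  counts <- rpois(1e4, 2)
  st <- hairpin_count_statistics(counts)
  expect_equal(st$lambda, 2, tolerance = 0.025)
  expect_equal(st$mean, st$lambda)
  # empirical PDF close to the fitted Poisson PDF
  expect_lt(max(abs(st$pdf$p_emp - st$pdf$p_pois)), 0.02)
})

test_that("track linking: stationary, hopping and pair-creation fixtures", {
  # one stationary hairpin over 100 frames -> one track spanning them
  rec <- data.frame(frame = 1:100, s = 10, polarity = 0.5)
  tr <- link_hairpin_tracks(rec, N = 20)
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(nrow(tr$points), 100)
  # deterministic +1 bond/frame hop: one track whose contour position
  # follows the frame index
  rec2 <- data.frame(frame = 1:12, s = 4 + 1:12, polarity = -0.5)
  tr2 <- link_hairpin_tracks(rec2, N = 30)
  expect_equal(nrow(tr2$tracks), 1)
  expect_equal(tr2$points$s, 4 + 1:12)
  # two simultaneous mid-chain births with opposite polarity are a pair
  # creation; a birth at the chain end is an end entry
  rec3 <- rbind(data.frame(frame = 5:20, s = 10, polarity = 0.5),
                data.frame(frame = 5:20, s = 15, polarity = -0.5),
                data.frame(frame = 8:20, s = 2, polarity = 0.5))
  tr3 <- link_hairpin_tracks(rec3, N = 30)
  expect_equal(nrow(tr3$tracks), 3)
  expect_equal(sort(tr3$tracks$birth_type),
               c("end_entry", "pair_creation", "pair_creation"))
  # a jump beyond max_jump breaks the track in two
  rec4 <- data.frame(frame = 1:10, s = c(rep(5, 5), rep(15, 5)),
                     polarity = 0.5)
  tr4 <- link_hairpin_tracks(rec4, N = 30, max_jump = 4)
  expect_equal(nrow(tr4$tracks), 2)
})

test_that("polarity bookkeeping: imbalance changes only via end events", {
  # pair events change both polarities together, so the imbalance
  # (#+1/2 - #-1/2) per frame changes only when an end event occurs
  rec <- rbind(data.frame(frame = 1:10, s = 10, polarity = 0.5),
               data.frame(frame = 1:10, s = 16, polarity = -0.5),
               data.frame(frame = 6:10, s = 2, polarity = -0.5))
  imb <- vapply(1:10, function(f) sum(rec$polarity[rec$frame == f]),
                numeric(1))
  expect_equal(unique(imb[1:5]), 0)
  expect_equal(unique(imb[6:10]), -0.5)
  tr <- link_hairpin_tracks(rec, N = 30)
  new_track <- tr$tracks[tr$tracks$birth_frame == 6, ]
  expect_equal(new_track$birth_type, "end_entry")
})

test_that("hairpin diffusivity recovers synthetic walks", {
  # deterministic alternating +/-1 hop: MSD alternates b^2, 0, b^2, ...;
  # the same weighted fit applied to the exact MSD of that process is the
  # closed-form reference
  b <- 0.89
  s <- 10 + rep(c(0, 1), 50)[1:80]
  pts <- data.frame(track = 1, frame = 1:80, s = s)
  est <- hairpin_diffusivity(pts, b = b, dt_frame = 1, lags = 1:6)
  msd_exact <- b^2 * (1:6 %% 2)
  n_pairs <- 80 - (1:6)
  fit_ref <- sum(n_pairs * msd_exact * (1:6)) / sum(n_pairs * (1:6)^2) / 2
  expect_equal(est$D_H, fit_ref, tolerance = 0.05)
  # unbiased lattice walk with hop probability p per frame:
  # D_H = b^2 p / 2 per unit frame time
  set.seed(33)
  p <- 0.4
  nfr <- 4000
  hops <- sample(c(-1, 0, 1), nfr, replace = TRUE,
                 prob = c(p / 2, 1 - p, p / 2))
  pts2 <- data.frame(track = 1, frame = 1:nfr, s = 50 + cumsum(hops))
  est2 <- hairpin_diffusivity(pts2, b = b, dt_frame = 1, lags = 1:8)
  expect_equal(est2$D_H, b^2 * p / 2, tolerance = 0.1)
  # too-short tracks yield a flagged NA
  est3 <- hairpin_diffusivity(pts2[1:3, ], lags = 1:8)
  expect_true(is.na(est3$D_H))
})
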