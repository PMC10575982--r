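test_that("oxDNA reader parses a hand-written fixture with unit
          conversion", {
  top <- withr::local_tempfile(fileext = ".top")
  conf <- withr::local_tempfile(fileext = ".conf")
  writeLines(c("3 1", "1 A -1 1", "1 A 0 2", "1 A 1 -1"), top)
  row <- function(x, y, z)
    paste(x, y, z, "1 0 0 0 1 0 0 0 0 0 0 0")
  writeLines(c("t = 1000", "b = 50 50 50", "E = 0 0 0",
               row(1, 2, 3), row(4, 5, 6), row(7, 8, 9),
               "t = 2000", "b = 50 50 50", "E = 0 0 0",
               row(1.5, 2, 3), row(4, 5.5, 6), row(7, 8, 9.5)), conf)
  traj <- read_oxdna(top, conf)
  expect_equal(dim(traj$positions), c(2, 3, 3))
  expect_equal(traj$positions[1, 1, ], c(1, 2, 3) * 0.8518)
  expect_equal(traj$positions[2, 2, ], c(4, 5.5, 6) * 0.8518)
  # header "t = 1000" with the 3.03 ps time unit -> 3030 ps
  expect_equal(traj$time_ps, c(3030, 6060))
})

test_that("oxDNA reader rejects malformed input with location info", {
  top <- withr::local_tempfile(fileext = ".top")
  conf <- withr::local_tempfile(fileext = ".conf")
  writeLines(c("2 1", "1 A -1 1", "1 A 0 -1"), top)
  row <- "1 2 3 1 0 0 0 1 0 0 0 0 0 0 0"
  # truncated final frame
  writeLines(c("t = 0", "b = 50 50 50", "E = 0 0 0", row, row,
               "t = 10", "b = 50 50 50", "E = 0 0 0", row), conf)
  expect_error(read_oxdna(top, conf), "truncated frame 2")
  # wrong column count
  writeLines(c("t = 0", "b = 50 50 50", "E = 0 0 0", row, "1 2 3"), conf)
  expect_error(read_oxdna(top, conf), "15 columns")
  # count mismatch vs topology
  writeLines(c("5 1"), top)
  expect_error(read_oxdna(top, conf), "fewer nucleotides")
})

test_that("write-then-read round trip reproduces positions and times", {
  base <- gen_helix_points(20, 40, 2, 26, "right", 0, seed = 1)
  traj <- gen_trajectory(base, fluct_sigma = 1, n_frames = 4, seed = 2)
  top <- withr::local_tempfile(fileext = ".top")
  conf <- withr::local_tempfile(fileext = ".conf")
  write_oxdna(traj, top, conf)
  back <- read_oxdna(top, conf)
  expect_equal(back$positions, traj$positions, tolerance = 1e-7)
  expect_equal(back$time_ps, traj$time_ps, tolerance = 1e-7)
})

test_that("rmsd_trace matches the brute-force oracle and known cases", {
  set.seed(9)
  pos <- array(rnorm(5 * 7 * 3), dim = c(5, 7, 3))
  traj <- cg_trajectory(pos, time_ps = 0:4)
  r <- rmsd_trace(traj)
  expect_equal(r$rmsd_nm, oracle_rmsd(pos), tolerance = 1e-12)
  expect_equal(r$rmsd_nm[1], 0)
  # rigid translation by 5 nm -> RMSD exactly 5 (no superposition)
  pos2 <- pos
  for (k in 2:5) pos2[k, , ] <- pos[1, , ] + 5 / sqrt(3)
  r2 <- rmsd_trace(cg_trajectory(pos2, 0:4))
  expect_equal(r2$rmsd_nm[-1], rep(5, 4), tolerance = 1e-12)
  # the aligned variant removes the translation
  r2a <- rmsd_trace(cg_trajectory(pos2, 0:4), align = TRUE)
  expect_equal(r2a$rmsd_nm[-1], rep(0, 4), tolerance = 1e-12)
})

test_that("rmsd of iid Gaussian displacement approaches sigma * sqrt(3)", {
  base <- matrix(0, 1000, 3)
  pos <- array(0, dim = c(2, 1000, 3))
  set.seed(4)
  pos[2, , ] <- matrix(rnorm(3000, 0, 2), 1000, 3)
  r <- rmsd_trace(cg_trajectory(pos, 0:1))
  expect_equal(r$rmsd_nm[2], 2 * sqrt(3), tolerance = 0.02)
})

test_that("rmsf matches the brute-force oracle and the chi expectation", {
  set.seed(10)
  pos <- array(rnorm(5 * 7 * 3), dim = c(5, 7, 3))
  traj <- cg_trajectory(pos, time_ps = 0:4)
  expect_equal(rmsf(traj, window_ns = c(-1, 1)), oracle_rmsf(pos),
               tolerance = 1e-12)
  # static trajectory -> all zeros
  posc <- array(1, dim = c(3, 4, 3))
  expect_equal(rmsf(cg_trajectory(posc, 0:2), c(-1, 1)), rep(0, 4))
  # iid Gaussian fluctuation: per-entity RMSF ~ sigma * sqrt(3)
  traj2 <- gen_trajectory(matrix(0, 50, 3), fluct_sigma = 1.5,
                          n_frames = 100, seed = 6)
  f <- rmsf(traj2, window_ns = c(-1, 1e9))
  expect_equal(mean(f), 1.5 * sqrt(3), tolerance = 0.05)
  expect_true(all(abs(f / (1.5 * sqrt(3)) - 1) < 0.25))
})

test_that("the 2000-3000 ns window selects exactly 100 frames at 10 ns
          spacing", {
  traj <- gen_trajectory(matrix(0, 3, 3), fluct_sigma = 0.1,
                         n_frames = 301, frame_spacing_ns = 10, seed = 7)
  t_ns <- traj$time_ps / 1e3
  sel <- sum(t_ns > 2000 & t_ns <= 3000)
  expect_equal(sel, 100)
  expect_length(rmsf(traj), 3)
})

test_that("average_guide_points reduces 26 entities to 13 midpoints", {
  frame <- matrix(rnorm(26 * 3), 26, 3)
  pairs <- cbind(1:13, 14:26)
  gp <- average_guide_points(frame, pairs)
  expect_equal(dim(gp), c(13, 3))
  expect_equal(gp[4, ], (frame[4, ] + frame[17, ]) / 2)
  # identical pair -> that point; symmetric pair -> origin
  expect_equal(average_guide_points(frame, cbind(c(2, 2), c(2, 5)))[1, ],
               frame[2, ])
  sym <- rbind(c(1, 2, 3), c(-1, -2, -3))
  expect_equal(average_guide_points(sym, cbind(1, 2))[1, ], c(0, 0, 0))
  expect_error(average_guide_points(frame, cbind(1, 27)), "out of range")
})

test_that("fit_helix recovers radius, pitch and handedness exactly on
          noiseless helices", {
  pts <- gen_helix_points(20, 40, 2, 13, "right", 0, seed = 1)
  fit <- fit_helix(pts)
  expect_equal(fit$radius, 20, tolerance = 1e-6)
  expect_equal(fit$pitch, 40, tolerance = 1e-6)
  expect_equal(fit$turns, 2, tolerance = 1e-6)
  expect_equal(fit$handedness, "right")
  expect_lt(fit$rms, 1e-6)
  # mirror image: same radius and pitch, opposite handedness
  m <- pts
  m[, 2] <- -m[, 2]
  fm <- fit_helix(m)
  expect_equal(fm$radius, 20, tolerance = 1e-6)
  expect_equal(fm$pitch, 40, tolerance = 1e-6)
  expect_equal(fm$handedness, "left")
  # the anti-GQ-NS mean curvature radius is recovered exactly
  pa <- gen_helix_points(25.8, 39, 3.5, 200, "right", 0, seed = 2)
  expect_equal(fit_helix(pa)$radius, 25.8, tolerance = 1e-6)
  expect_error(fit_helix(pts[1:3, ]), "at least 4")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_helix(line), "collinear")
})

test_that("fit_helix is rigid-motion invariant", {
  pts <- gen_helix_points(20, 40, 2, 13, "right", 0.3, seed = 3)
  f0 <- fit_helix(pts)
  th <- c(0.4, -1.1, 0.8)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0,
                 -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  moved <- sweep(pts %*% Rx %*% Rz, 2, c(100, -50, 8), `+`)
  f1 <- fit_helix(moved)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-5)
  expect_equal(f1$pitch, f0$pitch, tolerance = 1e-5)
  expect_equal(f1$handedness, f0$handedness)
  # the axis transforms covariantly
  expect_equal(abs(sum(f1$axis_direction %*% t(Rx %*% Rz) *
                         f0$axis_direction)),
               1, tolerance = 1e-4)
})

test_that("helix parameter recovery degrades gracefully with noise", {
  errs <- vapply(c(0, 0.5, 1), function(sig) {
    e <- vapply(1:8, function(s) {
      pts <- gen_helix_points(20, 40, 2, 13, "right", sig, seed = s)
      abs(fit_helix(pts)$radius - 20)
    }, numeric(1))
    median(e)
  }, numeric(1))
  expect_lt(errs[1], 1e-8)
  expect_lt(errs[2], 0.5)
  expect_lt(errs[3], 1)
})

test_that("backbone/pier radius comparison implements the inside-outside
          dichotomy", {
  b <- gen_helix_points(20, 40, 2, 13, "right", 0, seed = 1)
  p <- gen_helix_points(26, 40, 2, 13, "right", 0, seed = 1)
  fb <- fit_helix(b)
  fp <- fit_helix(p)
  cmp <- compare_backbone_pier(fb, fp)
  expect_equal(cmp$difference, 6, tolerance = 1e-5)
  expect_equal(cmp$call, "backbone-inside")
  rev <- compare_backbone_pier(fp, fb)
  expect_equal(rev$difference, -cmp$difference, tolerance = 1e-9)
  expect_equal(rev$call, "backbone-outside")
  expect_equal(compare_backbone_pier(fb, fb)$call, "indeterminate")
  # incompatible axes are rejected
  tilted <- fit_helix(b %*% matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3))
  expect_error(compare_backbone_pier(fb, tilted), "incompatible")
})
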