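test_that("corr2d matches the Pearson formula and its analytic cases", {
  a <- frame_abcd()
  # self-correlation and affine invariance
  expect_equal(corr2d(a, a), 1, tolerance = 1e-12)
  expect_equal(corr2d(a, 3 * a + 7), 1, tolerance = 1e-12)
  expect_equal(corr2d(a, -a + 2), -1, tolerance = 1e-12)
  # hand-summed Pearson over the 4 pixel pairs: r = 4/5
  b <- matrix(c(1, 4, 2, 3), 2, 2)  # rows: [1 2; 4 3]
  expect_equal(corr2d(a, b), 0.8, tolerance = 1e-12)
})

test_that("corr2d rejects degenerate input instead of returning 0", {
  a <- frame_abcd()
  expect_error(corr2d(a, matrix(5, 2, 2)), "zero intensity variance")
  expect_error(corr2d(a, matrix(1:6, 2, 3)), "dimensions differ")
  m <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_error(corr2d(a, a, mask = m), "at least 2 pixels")
})

test_that("corr2d is symmetric and bounded on random pairs", {
  set.seed(42)
  for (i in 1:1000) {
    a <- matrix(rnorm(36), 6, 6)
    b <- matrix(rnorm(36), 6, 6)
    r1 <- corr2d(a, b)
    expect_identical(r1, corr2d(b, a))
    expect_lte(abs(r1), 1)
  }
})

test_that("mean_abs_diff enumerated cases and metric properties hold", {
  a <- frame_abcd()
  expect_identical(mean_abs_diff(a, a), 0)
  expect_equal(mean_abs_diff(matrix(0, 3, 3), matrix(1, 3, 3)), 1)
  # mean of {1,1,3,5} = 2.5
  x <- matrix(c(0, 4, 2, 6), 2, 2)  # rows: [0 2; 4 6]
  expect_equal(mean_abs_diff(x, matrix(1, 2, 2)), 2.5, tolerance = 1e-12)
  # triangle inequality on random triples
  set.seed(7)
  for (i in 1:200) {
    p <- matrix(rnorm(25), 5, 5); q <- matrix(rnorm(25), 5, 5)
    r <- matrix(rnorm(25), 5, 5)
    expect_lte(mean_abs_diff(p, r),
               mean_abs_diff(p, q) + mean_abs_diff(q, r) + 1e-12)
  }
})

test_that("framewise_dynamics averages each frame against all others", {
  A <- frame_abcd()
  stack <- timelapse_stack(list(A, A, A + 5))
  d <- framewise_dynamics(stack)
  # affine shifts leave correlation at 1; differences enumerate the 2 pairs
  expect_equal(d$per_frame_correlation, rep(1, 3), tolerance = 1e-12)
  expect_equal(d$per_frame_difference, c(2.5, 2.5, 5), tolerance = 1e-12)
  expect_equal(d$stack_correlation, 1, tolerance = 1e-12)
  expect_equal(d$stack_difference, mean(c(2.5, 2.5, 5)), tolerance = 1e-12)
  expect_identical(d$n_frames, 3L)
})

test_that("identical frames give correlation 1 and difference 0", {
  A <- matrix(rnorm(64), 8, 8)
  d <- framewise_dynamics(timelapse_stack(list(A, A, A, A)))
  expect_equal(d$stack_correlation, 1, tolerance = 1e-12)
  expect_identical(d$stack_difference, 0)
})

test_that("a zero-variance frame is reported by index", {
  A <- frame_abcd()
  expect_error(framewise_dynamics(timelapse_stack(list(A, matrix(2, 2, 2), A))),
               "frame 2 has zero intensity variance")
})

test_that("time reversal reverses per-frame lists and keeps summaries", {
  set.seed(11)
  frames <- lapply(1:6, function(i) matrix(rnorm(100), 10, 10))
  fwd <- framewise_dynamics(timelapse_stack(frames))
  rev_ <- framewise_dynamics(timelapse_stack(rev(frames)))
  expect_equal(rev_$per_frame_correlation, rev(fwd$per_frame_correlation))
  expect_equal(rev_$per_frame_difference, rev(fwd$per_frame_difference))
  expect_equal(rev_$stack_correlation, fwd$stack_correlation)
  expect_equal(rev_$stack_difference, fwd$stack_difference)
})

test_that("pure-noise stacks have near-zero expected correlation", {
  # Monte-Carlo null: 25 frames of independent Gaussian noise per stack
  set.seed(123)
  grand <- mean(vapply(1:100, function(i) {
    frames <- lapply(1:25, function(j) matrix(rnorm(256), 16, 16))
    framewise_dynamics(timelapse_stack(frames))$stack_correlation
  }, numeric(1)))
  expect_lt(abs(grand), 0.02)
})

test_that("masking restricts the metrics to the cell area", {
  A <- matrix(rnorm(100), 10, 10)
  B <- A
  B[1:5, ] <- B[1:5, ] + matrix(rnorm(50), 5, 10)  # perturb outside the mask
  mask <- matrix(FALSE, 10, 10); mask[6:10, ] <- TRUE
  d <- framewise_dynamics(timelapse_stack(list(A, B), cell_mask = mask))
  expect_equal(d$stack_correlation, 1, tolerance = 1e-12)
  expect_identical(d$stack_difference, 0)
})

test_that("the lag profile aggregates pairs by frame separation", {
  set.seed(5)
  frames <- lapply(1:5, function(i) matrix(rnorm(64), 8, 8))
  d <- framewise_dynamics(timelapse_stack(frames, frame_interval = 2.5),
                          lag_profile = TRUE)
  expect_identical(d$by_lag$lag, 1:4)
  expect_equal(d$by_lag$seconds, (1:4) * 2.5)
  # lag-1 mean equals direct enumeration of consecutive pairs
  direct <- mean(vapply(1:4, function(i) corr2d(frames[[i]], frames[[i + 1]]),
                        numeric(1)))
  expect_equal(d$by_lag$correlation[1], direct, tolerance = 1e-12)
})

test_that("overlay_rgb scales channels and handles degenerate range", {
  A <- frame_abcd()
  st <- timelapse_stack(list(A, A, A))
  ov <- overlay_rgb(st, c(1, 2, 3))
  # identical frames: gray/white overlay with R = G = B
  expect_equal(ov[, , 1], ov[, , 2])
  expect_equal(ov[, , 2], ov[, , 3])
  expect_equal(range(ov), c(0, 1))
  # constant frames map to black under the 0-range convention
  z <- matrix(0, 2, 2)
  st0 <- timelapse_stack(list(z, z, A))
  expect_error(framewise_dynamics(st0), "zero intensity variance")  # guard only on metrics
  ov0 <- overlay_rgb(st0, c(1, 2, 3))
  expect_identical(ov0[, , 1], z)
  expect_identical(ov0[, , 2], z)
  expect_error(overlay_rgb(st, c(1, 2, 9)), "out of range")
})
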