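test_that("a frozen network with no noise renders identical frames", {
  sim <- make_filament_timelapse(image_size = c(48, 48), n_filaments = 8,
                                 length_range = c(10, 30),
                                 remodeling_rate = 0, noise_sigma = 0,
                                 n_frames = 5, seed = 3)
  for (t in 2:5) {
    expect_identical(sim$stack$frames[[t]], sim$stack$frames[[1]])
  }
  # per-pixel between-frame variance is exactly zero
  pix <- sapply(sim$stack$frames, as.vector)
  expect_identical(max(apply(pix, 1, var)), 0)
})

test_that("the filament generator is a pure function of its seed", {
  args <- list(image_size = c(48, 48), n_filaments = 50, remodeling_rate = 1,
               length_range = c(10, 30),
               noise_sigma = 0.05, n_frames = 6, seed = 99)
  s1 <- do.call(make_filament_timelapse, args)
  s2 <- do.call(make_filament_timelapse, args)
  expect_identical(s1$stack$frames, s2$stack$frames)
  # and it leaves the caller's RNG stream untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(do.call(make_filament_timelapse, args))
  expect_identical(rnorm(1), before)
})

test_that("faster remodeling lowers the all-pairs frame correlation", {
  # Monte-Carlo oracle: paired replicate simulations at p = 0.1 vs 0.5
  corr_at <- function(p, s) {
    sim <- make_filament_timelapse(image_size = c(48, 48), n_filaments = 12,
                                   length_range = c(10, 30),
                                   remodeling_rate = p, n_frames = 8, seed = s)
    framewise_dynamics(sim$stack)$stack_correlation
  }
  wins <- vapply(1:20, function(s) corr_at(0.5, s) < corr_at(0.1, s), logical(1))
  expect_gte(sum(wins), 19)
})

test_that("filament parameter validation rejects degenerate geometry", {
  expect_error(make_filament_timelapse(remodeling_rate = 1.2), "\\[0, 1\\]")
  expect_error(make_filament_timelapse(n_frames = 1), ">= 2")
  expect_error(make_filament_timelapse(image_size = c(32, 32),
                                       length_range = c(10, 500)),
               "exceeds the image diagonal")
  expect_error(make_filament_timelapse(bundling_factor = 0), "integer >= 1")
})

test_that("noiseless FRAP traces satisfy the closed-form model exactly", {
  mf <- 0.7; th <- 5; fpre <- 100; depth <- 0.7
  sim <- make_frap_trace(pre_bleach_level = fpre, bleach_depth = depth,
                         mobile_fraction = mf, t_half = th, noise_sigma = 0,
                         n_frames = 41, seed = 1)
  tr <- sim$trace
  post <- tr$times >= 0
  f0 <- fpre * (1 - depth)
  model <- f0 + mf * (fpre - f0) * (1 - exp(-tr$times[post] * log(2) / th))
  expect_equal(tr$intensities[post], model, tolerance = 1e-12)
  expect_equal(tr$intensities[!post], rep(fpre, 3), tolerance = 1e-12)
  # half the recovery span is reached at exactly t = t_half
  at_thalf <- tr$intensities[tr$times == th]
  expect_equal(at_thalf, f0 + mf * 0.5 * (fpre - f0), tolerance = 1e-12)
})

test_that("FRAP limits: full recovery plateau and immobile floor", {
  full <- make_frap_trace(mobile_fraction = 1, t_half = 0.01, noise_sigma = 0,
                          n_frames = 41, seed = 1)
  expect_equal(tail(full$trace$intensities, 1), 100, tolerance = 1e-6)
  flat <- make_frap_trace(mobile_fraction = 0, bleach_depth = 0.7,
                          noise_sigma = 0, seed = 1)
  post <- flat$trace$times >= 0
  expect_equal(flat$trace$intensities[post],
               rep(30, sum(post)), tolerance = 1e-12)
})

test_that("acquisition bleaching attenuates the whole series geometrically", {
  sim <- make_frap_trace(acquisition_bleach_rate = 0.01, noise_sigma = 0,
                         mobile_fraction = 0, n_frames = 10, seed = 1)
  raw <- make_frap_trace(acquisition_bleach_rate = 0, noise_sigma = 0,
                         mobile_fraction = 0, n_frames = 10, seed = 1)
  ratio <- sim$trace$intensities / raw$trace$intensities
  expect_equal(ratio, 0.99^(seq_along(ratio) - 1), tolerance = 1e-12)
})

test_that("blob fields carry an exact ground-truth table", {
  blank <- make_bfa_image(n_bodies = 0, seed = 1)
  expect_identical(nrow(blank$truth), 0L)
  expect_true(all(blank$image == blank$image[1, 1]))

  sim <- make_bfa_image(image_size = c(96, 96), n_bodies = 8, noise_sigma = 0,
                        seed = 5)
  # recompute each body's area and mean from the noiseless image
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    R <- row(sim$image); C <- col(sim$image)
    disk <- (R - tr$center_row)^2 + (C - tr$center_col)^2 <= tr$radius^2
    expect_identical(sum(disk), as.integer(tr$area_px))
    expect_equal(mean(sim$image[disk]), tr$mean_intensity, tolerance = 1e-12)
  }
  # brute-force pixel enumeration of a radius-3 disk at the center of 64x64
  one <- make_bfa_image(image_size = c(64, 64), n_bodies = 1,
                        radius_range = c(3, 3), noise_sigma = 0, seed = 2)
  enum <- sum(outer(-64:64, -64:64,
                    function(dy, dx) dy^2 + dx^2 <= 9))
  expect_identical(as.integer(one$truth$area_px), as.integer(enum))
})

test_that("infeasible blob packings fail loudly", {
  expect_error(make_bfa_image(image_size = c(40, 40), n_bodies = 50,
                              radius_range = c(6, 8), seed = 1),
               "packing infeasible")
})

test_that("allele-count simulation honours genotype probabilities and seed", {
  sim <- make_allele_counts(n_sites = 500, genotype_mix = c(0.3, 0.3, 0.4),
                            error_rate = 0, depth_min = 10, seed = 8)
  idx <- compute_snp_index(sim$counts)
  # with zero error: homozygous sites have index exactly 1, absent exactly 0
  expect_true(all(idx$snp_index[sim$truth$genotype == "hom"] == 1))
  expect_true(all(idx$snp_index[sim$truth$genotype == "absent"] == 0))
  expect_true(all(idx$depth >= 10))
  sim2 <- make_allele_counts(n_sites = 500, genotype_mix = c(0.3, 0.3, 0.4),
                             error_rate = 0, depth_min = 10, seed = 8)
  expect_identical(sim$counts, sim2$counts)
})
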