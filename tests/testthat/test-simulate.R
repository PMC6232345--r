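test_that("1/f generator hits the requested spectral exponent", {
  # white-noise limit
  x0 <- generate_one_over_f_series(4096, 1, gamma = 0, seed = 1)
  expect_lt(abs(periodogram_slope(x0, 1)), 0.1)
  # pink-noise exponents in the BOLD range, averaged over replicates
  for (gam in c(0.5, 1.0)) {
    xs <- generate_one_over_f_series(8192, 1, gamma = gam, seed = 2,
                                     n_series = 50)
    slopes <- apply(xs, 1, periodogram_slope, tr = 1)
    expect_equal(mean(slopes), -gam, tolerance = 0.1)
  }
})

test_that("1/f generator is deterministic, zero-mean, unit-SD", {
  a <- generate_one_over_f_series(512, 0.645, gamma = 0.8, seed = 9)
  b <- generate_one_over_f_series(512, 0.645, gamma = 0.8, seed = 9)
  expect_identical(a, b)
  expect_lt(abs(mean(a)), 1e-12)
  expect_equal(sd(a), 1, tolerance = 1e-12)
  expect_error(generate_one_over_f_series(512, 1, gamma = NaN, seed = 1),
               "finite")
  expect_error(generate_one_over_f_series(512, 1, gamma = Inf, seed = 1),
               "finite")
})

test_that("cluster signals are confined to their passband", {
  part <- rep(1:4, each = 5)
  cs <- generate_band_limited_cluster_signals(part, c(0.024, 0.048),
                                              900, 0.645, seed = 3)
  expect_equal(nrow(cs$signals), 4L)
  for (i in 1:4) {
    frac <- band_energy_fraction(cs$signals[i, ], 0.645, 0.024, 0.048)
    expect_gt(frac, 0.9)   # hard bin masking: essentially all energy inside
  }
  # distinct clusters get (near-)independent series
  expect_lt(max(abs(cor(t(cs$signals)) - diag(4))), 0.5)
})

test_that("full-band and degenerate passbands behave as specified", {
  nyq <- 1 / (2 * 0.645)
  cs <- generate_band_limited_cluster_signals(rep(1, 10), c(0, nyq),
                                              512, 0.645, seed = 4)
  expect_equal(nrow(cs$signals), 1L)   # one cluster -> one shared series
  expect_equal(band_energy_fraction(cs$signals[1, ], 0.645, 0, nyq), 1)
  expect_error(
    generate_band_limited_cluster_signals(rep(1, 10), c(0.05, 0.05),
                                          512, 0.645, seed = 1),
    "degenerate"
  )
})

test_that("pure-noise datasets have near-zero pairwise correlation", {
  cfg <- simulation_config(n_voxels = 40, n_subjects = 1,
                           n_timepoints = 512, seed = 5)
  sim <- synthesize_dataset(cfg)
  r <- cor(t(sim$datasets[[1]]$data))
  offdiag <- abs(r[upper.tri(r)])
  expect_lt(median(offdiag), 3 / sqrt(512))
})

test_that("a strong planted layer induces within-cluster correlation", {
  tp <- tiny_planted_sim(seed = 6)
  r <- cor(t(tp$sim$datasets[[1]]$data))
  same <- outer(tp$partition, tp$partition, "==")
  diag(same) <- NA
  expect_gt(mean(r[same & !is.na(same)]), mean(r[!same & !is.na(same)]) + 0.3)
})

test_that("subjects share shape and ground truth but not realizations", {
  cfg <- simulation_config(n_voxels = 30, n_subjects = 3,
                           n_timepoints = 256, seed = 8,
                           planted_layers = list(list(
                             passband = c(0.02, 0.06),
                             partition = rep(1:3, each = 10), amplitude = 1)))
  sim <- synthesize_dataset(cfg)
  expect_length(sim$datasets, 3L)
  dims <- lapply(sim$datasets, function(d) dim(d$data))
  expect_equal(dims[[1]], c(30L, 256L))
  expect_equal(dims[[1]], dims[[2]])
  expect_equal(dims[[2]], dims[[3]])
  expect_false(identical(sim$datasets[[1]]$data, sim$datasets[[2]]$data))
  # voxel series are z-scored
  expect_equal(unname(apply(sim$datasets[[1]]$data, 1, sd)), rep(1, 30),
               tolerance = 1e-12)
  # identical config+seed => bit-identical datasets
  expect_identical(sim, synthesize_dataset(cfg))
})

test_that("config validation guards invariants", {
  expect_error(simulation_config(10, 1, gamma = -1), "gamma")
  expect_error(simulation_config(10, 1, n_timepoints = 8), "16")
  expect_error(
    simulation_config(10, 1, planted_layers = list(list(
      passband = c(0.2, 2), partition = rep(1, 10), amplitude = 1))),
    "passband"
  )
  expect_error(
    simulation_config(10, 1, planted_layers = list(list(
      passband = c(0.02, 0.05), partition = rep(1, 3), amplitude = 1))),
    "label every voxel"
  )
  expect_error(simulation_config(1e5, 1, n_timepoints = 1000,
                                 max_elements = 1e6), "memory guard")
})

test_that("mask generator retains the requested fraction of voxels", {
  m1 <- generate_mask(c(10, 10, 10), 1, seed = 1)
  expect_true(all(m1))
  m <- generate_mask(c(10, 10, 10), 0.5, seed = 2)
  expect_equal(sum(m), 500L)
  expect_identical(m, generate_mask(c(10, 10, 10), 0.5, seed = 2))
  expect_error(generate_mask(c(4, 4), 0.001, seed = 1), "empty")
  # blobby, not salt-and-pepper: most retained voxels touch another one
  idx <- which(m, arr.ind = TRUE)
  nb <- vapply(seq_len(nrow(idx)), function(i) {
    any(rowSums(abs(sweep(idx[-i, , drop = FALSE], 2, idx[i, ]))) == 1)
  }, logical(1))
  expect_gt(mean(nb), 0.9)
})

test_that("NIfTI round-trip preserves data, mask order and ground truth", {
  tp <- tiny_planted_sim(seed = 12, n_voxels = 50, n_timepoints = 64,
                         n_subjects = 2)
  mask <- generate_mask(c(6, 6, 6), 50 / 216, seed = 3)
  dir <- withr::local_tempdir()
  write_dataset_nifti(tp$sim, mask, dir)
  back <- read_dataset_nifti(dir)
  expect_equal(back$mask, mask)
  expect_equal(back$datasets[[1]]$data, tp$sim$datasets[[1]]$data,
               tolerance = 1e-6)
  expect_equal(back$ground_truth$layers$partition[[1]], tp$partition)
  expect_equal(back$ground_truth$tr_seconds, 0.645)
})
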