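fs_study <- 1 / 0.645

test_that("packet addresses validate and round-trip through strings", {
  a <- packet_address(6, 1)
  expect_equal(format(a), "D6P1")
  expect_equal(parse_packet_address("D6P1"), a)
  expect_error(packet_address(3, 8), "0 .. 2\\^depth - 1")
  expect_error(packet_address(-1, 0), "non-negative")
  expect_error(parse_packet_address("P1D6"), "D5P1")
})

test_that("frequency ordering is the binary-reflected Gray code", {
  expect_equal(frequency_order_positions(0), 0L)
  expect_equal(frequency_order_positions(1), c(0L, 1L))
  expect_equal(frequency_order_positions(2), c(0L, 1L, 3L, 2L))
  expect_equal(frequency_order_positions(3), c(0L, 1L, 3L, 2L, 6L, 7L, 5L, 4L))
  # a permutation composed with its inverse is the identity
  for (d in 2:6) {
    perm <- frequency_order_positions(d) + 1L
    expect_equal(order(perm)[perm], seq_len(2^d))
  }
})

test_that("packet passbands follow the dyadic band formula", {
  expect_equal(packet_passband("D0P0", 1.5504), c(0, 0.7752))
  expect_equal(packet_passband("D2P3", 1.5504), c(0.5814, 0.7752))
  # the 12-24 mHz slow band at the study's sampling rate
  expect_equal(round(packet_passband("D6P1", fs_study) * 1000),
               c(12, 24))
})

test_that("full decomposition yields every node with the input at the root", {
  x <- matrix(rnorm(3 * 900), 3)
  tree <- wpt_decompose(x, fs = fs_study, max_depth = 6)
  expect_equal(n_packets(tree), 127L)
  expect_equal(packet_coefficients(tree, "D0P0"), x)
  # depth-6 nodes of a 900-sample series hold 15 coefficients (ceil-halving)
  expect_equal(ncol(packet_coefficients(tree, "D6P0")), 15L)
  expect_error(wpt_decompose(rnorm(32), fs = 1, max_depth = 6), "2\\^max_depth")
})

test_that("a constant series is isolated in the DC lineage", {
  tree <- wpt_decompose(rep(2.5, 256), fs = 1, max_depth = 5)
  for (d in 1:5) {
    for (p in 1:(2^d - 1)) {
      expect_lt(max(abs(packet_coefficients(tree, packet_address(d, p)))),
                1e-10)
    }
    e0 <- sum(packet_coefficients(tree, packet_address(d, 0))^2)
    expect_equal(e0, 256 * 2.5^2, tolerance = 1e-10)
  }
})

test_that("energy is conserved at every depth (dyadic length)", {
  x <- rnorm(512)
  tree <- wpt_decompose(x, fs = 1, max_depth = 6)
  e_in <- sum(x^2)
  for (d in 0:6) {
    e_d <- sum(vapply(0:(2^d - 1), function(p) {
      sum(packet_coefficients(tree, packet_address(d, p))^2)
    }, numeric(1)))
    expect_equal(e_d, e_in, tolerance = 1e-8)
  }
  # per-depth coefficient counts tile the signal exactly
  for (d in 0:6) {
    expect_equal(sum(vapply(0:(2^d - 1), function(p) {
      ncol(packet_coefficients(tree, packet_address(d, p)))
    }, numeric(1))), 512)
  }
})

test_that("a pure sinusoid lands in the packet its frequency predicts", {
  # 0.03 Hz at the study TR falls in D5P1 (24-48 mHz)
  s <- sin(2 * pi * 0.03 * (0:899) * 0.645)
  tree <- wpt_decompose(s, fs = fs_study, max_depth = 5)
  en <- vapply(0:31, function(p) {
    sum(packet_coefficients(tree, packet_address(5, p))^2)
  }, numeric(1))
  expect_equal(which.max(en) - 1L, 1L)
})

test_that("sinusoid sweep: max-energy depth-6 packet brackets the tone", {
  set.seed(11)
  hits <- 0L
  for (i in 1:20) {
    f0 <- runif(1, 0.02, fs_study / 2 - 0.02)
    s <- sin(2 * pi * f0 * (0:899) * 0.645 + runif(1, 0, 2 * pi))
    tree <- wpt_decompose(s, fs = fs_study, max_depth = 6)
    en <- vapply(0:63, function(p) {
      sum(packet_coefficients(tree, packet_address(6, p))^2)
    }, numeric(1))
    pb <- packet_passband(packet_address(6, which.max(en) - 1L), fs_study)
    if (f0 >= pb[1] && f0 <= pb[2]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)   # edge leakage tolerated
})

test_that("reconstruction from a full depth is exact; empty set gives zero", {
  x <- matrix(rnorm(4 * 900), 4)
  tree <- wpt_decompose(x, fs = fs_study, max_depth = 6)
  for (d in c(3, 6)) {
    keep <- sprintf("D%dP%d", d, 0:(2^d - 1))
    xr <- wpt_reconstruct(tree, keep)
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
  }
  expect_equal(wpt_reconstruct(tree, character(0)),
               matrix(0, 4, 900))
})

test_that("reconstruction is linear over disjoint packet sets", {
  x <- rnorm(512)
  tree <- wpt_decompose(x, fs = 1, max_depth = 4)
  a <- c("D4P0", "D4P3", "D3P4")
  b <- c("D4P2", "D2P3")
  both <- wpt_reconstruct(tree, c(a, b))
  expect_equal(both, wpt_reconstruct(tree, a) + wpt_reconstruct(tree, b),
               tolerance = 1e-10)
})

test_that("overlapping packet subsets are rejected", {
  tree <- wpt_decompose(rnorm(256), fs = 1, max_depth = 4)
  expect_error(wpt_reconstruct(tree, c("D2P1", "D4P5")), "ancestor")
  expect_error(wpt_reconstruct(tree, c("D3P1", "D3P1")), "duplicate")
})

test_that("the six-packet wideband set is band-limited to ~12-194 mHz", {
  set.seed(5)
  for (i in 1:3) {
    x <- rnorm(900)
    tree <- wpt_decompose(x, fs = fs_study, max_depth = 6)
    wide <- drop(wpt_reconstruct(tree, default_wideband_packets()))
    inside <- band_energy_fraction(wide, 0.645, 0.012, 0.194)
    # db7 spectral leakage: depth-5/6 nodes of a 900-sample series hold only
    # ~15-30 coefficients against a 14-tap filter, so sidelobes carry a few
    # percent of energy even for an exact subspace projection
    expect_gt(inside, 0.90)
  }
})

test_that("voxel batching does not change per-voxel results", {
  x <- matrix(rnorm(6 * 256), 6)
  t_all <- wpt_decompose(x, fs = 1, max_depth = 4)
  t_one <- wpt_decompose(x[4, ], fs = 1, max_depth = 4)
  expect_equal(packet_coefficients(t_all, "D4P9")[4, , drop = FALSE],
               packet_coefficients(t_one, "D4P9"))
})
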