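test_that("partition entropy matches hand values", {
  expect_equal(partition_entropy(rep(1, 7)), 0)
  expect_equal(partition_entropy(c(1, 1, 2, 2)), 1)
  expect_equal(partition_entropy(c(1, 1, 1, 2)),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)))
  expect_equal(partition_entropy(c(1, 1, 1, 2)), 0.8112781, tolerance = 1e-6)
  # bounded by log2 of the cluster count
  set.seed(1)
  for (i in 1:20) {
    p <- random_partition(40, 6)
    h <- partition_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log2(length(unique(p))) + 1e-12)
  }
  expect_error(partition_entropy(integer(0)), "empty")
})

test_that("mutual information matches hand values and bounds", {
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(mutual_information(a, b), 0)   # all joint cells 1/4
  expect_equal(mutual_information(a, a), partition_entropy(a))
  expect_equal(mutual_information(a, rep(1, 4)), 0)
  set.seed(2)
  for (i in 1:20) {
    p <- random_partition(30, 4); q <- random_partition(30, 5)
    i_pq <- mutual_information(p, q)
    expect_gte(i_pq, -1e-12)
    expect_lte(i_pq, min(partition_entropy(p), partition_entropy(q)) + 1e-12)
  }
  expect_error(mutual_information(1:4, 1:5), "lengths")
})

test_that("variation of information matches hand values", {
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(variation_of_information(a, a), 0)
  expect_equal(variation_of_information(a, b), 2)   # H = 1 each, I = 0
  # coarsening by one binary split costs exactly its entropy
  expect_equal(variation_of_information(rep(1, 4), a), 1)
  expect_equal(variation_of_information(a, b),
               variation_of_information(b, a))
})

test_that("VI is a relabel-invariant metric", {
  set.seed(3)
  for (i in 1:60) {
    n <- sample(10:50, 1)
    p <- random_partition(n, 5); q <- random_partition(n, 5)
    r <- random_partition(n, 5)
    vpq <- variation_of_information(p, q)
    # symmetry and identity of indiscernibles under relabelling
    expect_equal(vpq, variation_of_information(q, p))
    relab <- sample(10:14)[p]
    expect_equal(variation_of_information(p, relab), 0)
    expect_equal(variation_of_information(relab, q), vpq)
    # triangle inequality
    expect_lte(vpq, variation_of_information(p, r) +
                 variation_of_information(r, q) + 1e-10)
    # bound
    expect_lte(vpq, 2 * log2(n) + 1e-12)
  }
  # normalized variant divides by log2(n)
  p <- c(1, 1, 2, 2); q <- c(1, 2, 1, 2)
  expect_equal(variation_of_information(p, q, normalized = TRUE), 1)
})

test_that("vi_matrix satisfies its invariants and tracks input order", {
  set.seed(4)
  parts <- list(a = random_partition(30, 4), b = random_partition(30, 4),
                c = random_partition(30, 4))
  m <- vi_matrix(parts)
  expect_equal(diag(m), c(a = 0, b = 0, c = 0))
  expect_equal(m, t(m))
  expect_true(all(m >= 0 & m <= 2 * log2(30)))
  perm <- vi_matrix(parts[c(3, 1, 2)])
  expect_equal(perm, m[c(3, 1, 2), c(3, 1, 2)])
  dup <- vi_matrix(list(x = parts$a, y = parts$a))
  expect_equal(unname(dup), matrix(0, 2, 2))
  expect_error(vi_matrix(list(random_partition(10, 2),
                              random_partition(12, 2))),
               "inconsistent")
  expect_error(vi_matrix(parts[1]), "at least 2")
})

test_that("coarse meta-clustering splits a block-diagonal VI matrix", {
  set.seed(5)
  base1 <- random_partition(50, 4)
  base2 <- random_partition(50, 4)
  jitter <- function(p, m) { p[sample(50, m)] <- 99L; p }
  parts <- list(
    p1 = base1, p2 = jitter(base1, 2), p3 = jitter(base1, 3),
    q1 = base2, q2 = jitter(base2, 2), q3 = jitter(base2, 3)
  )
  vi <- vi_matrix(parts)
  meta <- cluster_spectra(vi, mode = "coarse-local")
  expect_equal(length(unique(meta$labels)), 2L)
  expect_equal(unname(meta$labels[c("p2", "p3")]),
               rep(unname(meta$labels["p1"]), 2))
  expect_equal(unname(meta$labels[c("q2", "q3")]),
               rep(unname(meta$labels["q1"]), 2))
  expect_false(meta$labels["p1"] == meta$labels["q1"])
})

test_that("indistinguishable parcellations stay in one meta-cluster", {
  p <- c(1, 1, 2, 2, 3, 3)
  parts <- list(a = p, b = c(2, 2, 3, 3, 1, 1), c = p + 10L)
  vi <- vi_matrix(parts)      # exactly zero everywhere
  for (mode in c("coarse-local", "fine-global")) {
    meta <- cluster_spectra(vi, mode = mode)
    expect_equal(length(unique(meta$labels)), 1L)
  }
})

test_that("fine-global mode honours the designated packet subset", {
  set.seed(6)
  base1 <- random_partition(50, 4)
  base2 <- random_partition(50, 4)
  base3 <- random_partition(50, 4)
  jitter <- function(p, m) { p[sample(50, m)] <- 99L; p }
  parts <- list(
    lo1 = base1, lo2 = jitter(base1, 2),
    mid1 = base2, mid2 = jitter(base2, 2),
    hi1 = base3, hi2 = jitter(base3, 2)
  )
  vi <- vi_matrix(parts)
  fine <- cluster_spectra(vi, mode = "fine-global",
                          designated = c("lo1", "lo2", "mid1", "mid2"))
  # the designated low/mid bands are separated from one another
  expect_false(fine$labels["lo1"] == fine$labels["mid1"])
  expect_equal(unname(fine$labels["lo1"]), unname(fine$labels["lo2"]))
  expect_error(cluster_spectra(vi, mode = "fine-global",
                               designated = "nope"), "unknown")
})
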