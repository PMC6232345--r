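# Independent oracles used to cross-check the package implementations.
# Everything here is deliberately naive (brute force / direct formula) and
# shares no code path with the functions under test.

# Exhaustive O(n^3) UPGMA: maintains explicit index sets, recomputes every
# between-cluster mean distance from the original matrix at every step.
# Returns merge heights plus the label vector after each merge.
brute_upgma <- function(d) {
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h; best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    heights <- c(heights, best_h)
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    partitions <- c(partitions, list(canonical_labels(lab)))
  }
  list(heights = heights, partitions = partitions)
}

# relabel so clusters are numbered by first appearance, making label vectors
# comparable across implementations
canonical_labels <- function(lab) match(lab, unique(lab))

# OLS slope of log10 periodogram vs log10 frequency, DC excluded
periodogram_slope <- function(x, tr) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  k <- 1:(floor(n / 2))
  f <- k / (n * tr)
  keep <- p[k + 1] > 0
  stats::coef(stats::lm(log10(p[k + 1][keep]) ~ log10(f[keep])))[[2]]
}

# fraction of spectral energy inside [lo, hi] Hz (both spectral halves)
band_energy_fraction <- function(x, tr, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * tr)
  sum(p[f >= lo & f <= hi]) / sum(p)
}

# direct g = 2 inconsistency: each link's height against the heights of its
# direct sub-links, computed straight from the merge table with no windowing
# machinery
direct_g2_inconsistency <- function(tree) {
  nm <- nrow(tree$merge)
  vapply(seq_len(nm), function(k) {
    ch <- tree$merge[k, ]
    ch <- ch[ch > 0]
    win <- c(tree$height[k], tree$height[ch])
    if (length(win) < 2L) return(0)
    s <- stats::sd(win)
    if (s == 0) 0 else (tree$height[k] - mean(win)) / s
  }, numeric(1))
}

# random partition of n items into at most kmax non-empty-ish clusters
random_partition <- function(n, kmax) {
  sample.int(kmax, n, replace = TRUE)
}

# random symmetric distance matrix with zero diagonal, continuous entries
random_distance_matrix <- function(n) {
  pts <- matrix(stats::rnorm(n * 3), n)
  as.matrix(stats::dist(pts))
}

# tiny planted simulation reused by several module tests
tiny_planted_sim <- function(seed = 7L, n_voxels = 60L, n_timepoints = 256L,
                             n_subjects = 2L, amplitude = 3) {
  part <- rep(1:3, length.out = n_voxels)
  cfg <- simulation_config(
    n_voxels = n_voxels, n_subjects = n_subjects,
    n_timepoints = n_timepoints, seed = seed,
    planted_layers = list(list(passband = c(0.02, 0.06), partition = part,
                               amplitude = amplitude))
  )
  list(sim = synthesize_dataset(cfg), partition = part, config = cfg)
}
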