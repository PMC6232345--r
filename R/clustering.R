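#' Average-linkage (UPGMA) agglomerative clustering
#'
#' Merges the closest pair of clusters at every step, where the
#' between-cluster distance is the unweighted mean of all cross-pair voxel
#' distances,
#' \eqn{S_2(a,b) = \frac{1}{n_a n_b}\sum_{i\in a}\sum_{j\in b} S_1(i,j)}.
#' The merge structure is computed by [stats::hclust()] with
#' `method = "average"` and wrapped in a `linkage_tree` that records merge
#' children, heights `z(k)` and merged cluster sizes.
#'
#' @param distance_matrix Square symmetric matrix with zero diagonal (e.g.
#'   from [correlation_distance()]), or a [stats::dist] object.
#' @return A `linkage_tree`: list with `merge` (n-1 x 2, [stats::hclust()]
#'   convention: negative entries are leaves, positive entries earlier
#'   links), `height`, `size` (leaves under each link), and `n`.
#' @export
average_linkage <- function(distance_matrix) {
  d <- if (inherits(distance_matrix, "dist")) distance_matrix else {
    if (anyNA(distance_matrix) || any(!is.finite(distance_matrix))) {
      stop("distance matrix contains NaN/NA/Inf", call. = FALSE)
    }
    stats::as.dist(distance_matrix)
  }
  if (anyNA(d)) stop("distance matrix contains NaN/NA", call. = FALSE)
  hc <- stats::hclust(d, method = "average")
  linkage_tree(hc$merge, hc$height)
}

#' @rdname average_linkage
#' @param merge,height Merge table and link heights in [stats::hclust()]
#'   convention, for constructing a tree directly (e.g. hand-built
#'   fixtures).
#' @export
linkage_tree <- function(merge, height) {
  merge <- matrix(as.integer(merge), ncol = 2L)
  n <- nrow(merge) + 1L
  size <- integer(n - 1L)
  for (k in seq_len(n - 1L)) {
    s <- 0L
    for (c in merge[k, ]) s <- s + (if (c < 0L) 1L else size[c])
    size[k] <- s
  }
  structure(list(merge = merge, height = as.numeric(height), size = size,
                 n = n),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("<linkage_tree> ", x$n, " leaves, ", x$n - 1L, " links, heights [",
      signif(min(x$height), 4), ", ", signif(max(x$height), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
as.hclust.linkage_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = leaf_order(x),
         labels = NULL, method = "average", call = NULL,
         dist.method = "user"),
    class = "hclust"
  )
}

# leaves (positive voxel indices) under every link
link_leaf_sets <- function(tree) {
  nm <- nrow(tree$merge)
  sets <- vector("list", nm)
  for (k in seq_len(nm)) {
    out <- integer(0)
    for (c in tree$merge[k, ]) {
      out <- c(out, if (c < 0) -c else sets[[c]])
    }
    sets[[k]] <- out
  }
  sets
}

#' Dendrogram link inconsistency
#'
#' For every link `k`, compares its height `z(k)` with the heights of links
#' beneath it: `Y4(k) = (z(k) - Y1(k)) / Y2(k)`, where `Y1` is the mean and
#' `Y2` the sample (n-1) standard deviation of the comparison window. With a
#' finite `g` the window is `z(k)` plus the links up to `g - 1` levels
#' beneath `k` in the merge structure (so `g = 2` compares a link with its
#' direct sub-links, the widely used dendrogram-inconsistency convention);
#' with `g = "global"` the window is `z(k)` plus every link in the subtree.
#' `Y4 = 0` where the window has a single element or zero spread, so a link
#' over two leaves is never inconsistent. Large `Y4` marks a link whose
#' joined elements are far more dissimilar than anything joined beneath it —
#' a natural cleavage point.
#'
#' @param tree A `linkage_tree`.
#' @param g Window size: integer >= 2 for a local window, or `"global"` for
#'   the entire subtree.
#' @return Data frame with one row per link: `link`, `y1`, `y2`, `n_window`,
#'   `y4`.
#' @export
inconsistency <- function(tree, g = 2L) {
  stopifnot(inherits(tree, "linkage_tree"))
  global <- identical(g, "global") || identical(g, Inf)
  if (!global) {
    g <- as.integer(g)
    if (is.na(g) || g < 2L) stop("`g` must be an integer >= 2 or \"global\"", call. = FALSE)
  }
  z <- tree$height
  nm <- length(z)
  link_children <- lapply(seq_len(nm), function(k) {
    ch <- tree$merge[k, ]
    ch[ch > 0]
  })
  y1 <- y2 <- y4 <- numeric(nm)
  nw <- integer(nm)
  for (k in seq_len(nm)) {
    below <- integer(0)
    frontier <- link_children[[k]]
    lev <- 1L
    while (length(frontier) && (global || lev <= g - 1L)) {
      below <- c(below, frontier)
      frontier <- unlist(link_children[frontier], use.names = FALSE)
      lev <- lev + 1L
    }
    win <- c(z[k], z[below])
    nw[k] <- length(win)
    y1[k] <- mean(win)
    y2[k] <- if (length(win) > 1L) stats::sd(win) else 0
    y4[k] <- if (nw[k] < 2L || y2[k] == 0) 0 else (z[k] - y1[k]) / y2[k]
  }
  data.frame(link = seq_len(nm), y1 = y1, y2 = y2, n_window = nw, y4 = y4)
}

# cut the given links plus all their ancestors; remaining maximal subtrees
# (and orphaned leaves) become clusters, labelled 1..K by first voxel
prune_cut_links <- function(tree, cut_links) {
  nm <- nrow(tree$merge)
  removed <- logical(nm)
  removed[cut_links] <- TRUE
  for (k in seq_len(nm)) {
    ch <- tree$merge[k, ]
    ch <- ch[ch > 0]
    if (length(ch) && any(removed[ch])) removed[k] <- TRUE
  }
  labels <- seq_len(tree$n)       # union-find over leaves
  find <- function(i) {
    while (labels[i] != i) {
      labels[i] <<- labels[labels[i]]
      i <- labels[i]
    }
    i
  }
  reps <- vector("list", nm)      # representative leaf of each link's subtree
  for (k in seq_len(nm)) {
    ch <- tree$merge[k, ]
    r <- integer(2)
    for (i in 1:2) {
      r[i] <- if (ch[i] < 0) -ch[i] else reps[[ch[i]]]
    }
    reps[[k]] <- r[1]
    if (!removed[k]) {
      labels[find(r[2])] <- find(r[1])
    }
  }
  root <- vapply(seq_len(tree$n), find, 0L)
  out <- match(root, unique(root))
  as.integer(out)
}

#' Prune a dendrogram by inconsistency threshold
#'
#' Cuts every link whose inconsistency exceeds `threshold`, together with
#' all links above it (a cluster forms at a node only if the node and
#' everything beneath it is consistent). Each remaining maximal subtree, and
#' each orphaned leaf, becomes one cluster. A threshold below the minimum
#' gives all singletons; at or above the maximum, one cluster.
#'
#' @param tree A `linkage_tree`.
#' @param inconsistency_table Result of [inconsistency()] on `tree`.
#' @param threshold Finite cut level on `Y4`.
#' @return Integer cluster labels (contiguous from 1), with attributes
#'   `provenance` recording threshold and cut links.
#' @export
prune_by_inconsistency <- function(tree, inconsistency_table, threshold) {
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  cut <- inconsistency_table$link[inconsistency_table$y4 > threshold]
  labels <- prune_cut_links(tree, cut)
  attr(labels, "provenance") <- list(method = "inconsistency",
                                     threshold = threshold, cut_links = cut)
  labels
}

#' Prune a dendrogram to exactly k clusters
#'
#' Removes the `k - 1` last (highest) merges, i.e. the standard flat cut of
#' [stats::cutree()].
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Integer cluster labels (contiguous from 1).
#' @export
prune_to_k <- function(tree, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > tree$n) {
    stop("`k` must lie in 1 .. ", tree$n, call. = FALSE)
  }
  if (k == tree$n) {
    labels <- seq_len(tree$n)
  } else {
    cut <- if (k == 1L) integer(0) else seq(tree$n - k + 1L, tree$n - 1L)
    labels <- prune_cut_links(tree, cut)
  }
  labels <- match(labels, unique(labels))
  attr(labels, "provenance") <- list(method = "k", k = k)
  labels
}

#' Dendrogram-consistent leaf ordering
#'
#' Returns an ordering of the leaves in which the children of every merge
#' occupy contiguous spans — the 1-D projection used to arrange dendrogram
#' abscissas so related clusters sit adjacent and horizontal links stay
#' short. The traversal is deterministic (left child of each merge first).
#'
#' @param tree A `linkage_tree`.
#' @return Integer permutation of `1..n`.
#' @export
leaf_order <- function(tree) {
  stopifnot(inherits(tree, "linkage_tree"))
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(tree$merge[node, 1]), walk(tree$merge[node, 2]))
  }
  walk(nrow(tree$merge))
}
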