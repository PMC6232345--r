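#' Entropy of a partition
#'
#' `H(C) = -sum_i P(i) log2 P(i)` with `P(i) = |C_i| / n`, in bits.
#' `0 log 0` is taken as 0.
#'
#' @param partition Cluster labels (any atomic type; labels are arbitrary).
#' @return Entropy in bits, `0 <= H <= log2(#clusters)`.
#' @export
#' @examples
#' partition_entropy(c(1, 1, 2, 2))   # 1 bit
#' partition_entropy(c(1, 1, 1, 2))   # ~0.8113 bits
partition_entropy <- function(partition) {
  if (length(partition) == 0L) stop("empty partition", call. = FALSE)
  p <- table(partition) / length(partition)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two partitions
#'
#' `I(C', C'') = sum_ij P(i,j) log2( P(i,j) / (P(i) P(j)) )` with
#' `P(i,j) = |C'_i intersect C''_j| / n`, in bits; `0 log` terms are 0.
#'
#' @param partition_a,partition_b Cluster labels over the same voxels.
#' @return Mutual information in bits, `0 <= I <= min(H_a, H_b)`.
#' @export
mutual_information <- function(partition_a, partition_b) {
  if (length(partition_a) != length(partition_b)) {
    stop("partitions must label the same voxels (lengths ",
         length(partition_a), " vs ", length(partition_b), ")", call. = FALSE)
  }
  n <- length(partition_a)
  joint <- table(partition_a, partition_b) / n
  pa <- rowSums(joint)
  pb <- colSums(joint)
  outer_p <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Variation of information between two partitions
#'
#' Meila's metric on the space of partitions,
#' `VI(C', C'') = [H(C') - I(C', C'')] + [H(C'') - I(C', C'')]`, in bits:
#' the information lost plus the information gained when exchanging one
#' parcellation for the other. Zero iff the partitions are identical up to
#' relabelling; symmetric; satisfies the triangle inequality; bounded by
#' `2 log2 n`.
#'
#' @param partition_a,partition_b Cluster labels over the same voxels.
#' @param normalized Divide by `log2(n)` (off by default; the raw VI is
#'   reported everywhere in this package).
#' @return VI in bits (or a dimensionless fraction if `normalized`).
#' @export
#' @examples
#' variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 2 bits
variation_of_information <- function(partition_a, partition_b,
                                     normalized = FALSE) {
  i <- mutual_information(partition_a, partition_b)
  vi <- (partition_entropy(partition_a) - i) +
    (partition_entropy(partition_b) - i)
  vi <- max(vi, 0)          # clamp tiny negative rounding
  if (normalized) vi / log2(length(partition_a)) else vi
}

#' All-pairs VI matrix over a set of parcellations
#'
#' @param partitions Named list of label vectors over the same voxels (names
#'   typically packet addresses like `"D5P1"`).
#' @param normalized Passed to [variation_of_information()].
#' @return Symmetric matrix of VI in bits with zero diagonal, dimnames from
#'   `partitions`.
#' @export
vi_matrix <- function(partitions, normalized = FALSE) {
  np <- length(partitions)
  if (np < 2L) stop("need at least 2 partitions", call. = FALSE)
  nv <- unique(lengths(partitions))
  if (length(nv) != 1L) {
    stop("partitions have inconsistent voxel counts: ",
         paste(nv, collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, np, np, dimnames = list(names(partitions), names(partitions)))
  for (i in seq_len(np - 1L)) {
    for (j in seq(i + 1L, np)) {
      m[i, j] <- m[j, i] <- variation_of_information(
        partitions[[i]], partitions[[j]], normalized = normalized
      )
    }
  }
  m
}

#' Meta-clustering of subbands by VI between their parcellations
#'
#' Clusters the packets themselves, using the VI matrix as the distance,
#' with average linkage and inconsistency pruning — revealing which spectral
#' subbands produce mutually similar connectivity structure. Two pruning
#' modes:
#' \describe{
#'   \item{`"coarse-local"`}{cut exactly the link(s) attaining the single
#'     highest local (`g = 2`) inconsistency — the sharpest local jump in
#'     linkage distance splits the spectrum in two.}
#'   \item{`"fine-global"`}{with global (`g = "global"`) inconsistency,
#'     find the lowest link with positive inconsistency among links that
#'     join designated packets (both children contain at least one), and cut
#'     every link at least that inconsistent — a finer segmentation.}
#' }
#'
#' @param vi A VI matrix from [vi_matrix()].
#' @param mode `"coarse-local"` or `"fine-global"`.
#' @param designated For `"fine-global"`: packet names (or indices) defining
#'   the band of interest, e.g. the low-frequency packets; default all.
#' @return List with `labels` (meta-cluster label per packet, named),
#'   `mode`, `cut_links`, `tree` (the `linkage_tree`), and `inconsistency`.
#' @export
cluster_spectra <- function(vi, mode = c("coarse-local", "fine-global"),
                            designated = NULL) {
  mode <- match.arg(mode)
  tree <- average_linkage(vi)
  if (mode == "coarse-local") {
    inc <- inconsistency(tree, g = 2L)
    cut <- which(inc$y4 == max(inc$y4) & inc$y4 > 0)
  } else {
    inc <- inconsistency(tree, g = "global")
    des <- if (is.null(designated)) {
      seq_len(ncol(vi))
    } else if (is.character(designated)) {
      idx <- match(designated, colnames(vi))
      if (anyNA(idx)) {
        stop("unknown packet(s): ",
             paste(designated[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      idx
    } else {
      as.integer(designated)
    }
    sets <- link_leaf_sets(tree)
    eligible <- vapply(seq_len(nrow(tree$merge)), function(k) {
      ch <- tree$merge[k, ]
      both <- vapply(ch, function(c) {
        lv <- if (c < 0) -c else sets[[c]]
        any(lv %in% des)
      }, logical(1))
      all(both)
    }, logical(1))
    cand <- which(eligible & inc$y4 > 0)
    if (length(cand) == 0L) {
      cut <- integer(0)
    } else {
      first <- cand[order(tree$height[cand], cand)][1]
      cut <- which(inc$y4 >= inc$y4[first])
    }
  }
  labels <- prune_cut_links(tree, cut)
  names(labels) <- colnames(vi)
  list(labels = labels, mode = mode, cut_links = cut, tree = tree,
       inconsistency = inc)
}
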