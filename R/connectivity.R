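#' Concatenate one packet's coefficients across subjects
#'
#' Builds the group-level voxel x coefficient matrix for a single wavelet
#' packet by placing each subject's coefficient block side by side (subject
#' order, then coefficient order). By default each subject's block is
#' z-scored per voxel first, so between-subject amplitude differences do not
#' dominate the pooled correlations; set `zscore = FALSE` for raw pooling.
#'
#' @param per_subject List of voxel x coefficient matrices, one per subject,
#'   all with the same voxel count and coefficient count.
#' @param zscore Z-score each subject's rows before concatenating
#'   (default `TRUE`).
#' @return Voxel x (total coefficients) matrix with attributes `offsets`
#'   (0-based column offset of each subject's block) and `zscore`.
#' @export
concatenate_group <- function(per_subject, zscore = TRUE) {
  stopifnot(length(per_subject) >= 1L)
  nv <- nrow(per_subject[[1]])
  nc <- ncol(per_subject[[1]])
  for (s in seq_along(per_subject)) {
    if (nrow(per_subject[[s]]) != nv) {
      stop("subject ", s, " has ", nrow(per_subject[[s]]),
           " voxels; expected ", nv, call. = FALSE)
    }
    if (ncol(per_subject[[s]]) != nc) {
      stop("subject ", s, " has ", ncol(per_subject[[s]]),
           " coefficients; expected ", nc, call. = FALSE)
    }
  }
  blocks <- lapply(per_subject, function(m) {
    if (!zscore) return(m)
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    sdv[sdv == 0] <- 1      # flat rows stay flat; flagged downstream
    (m - mu) / sdv
  })
  out <- do.call(cbind, blocks)
  attr(out, "offsets") <- (seq_along(per_subject) - 1L) * nc
  attr(out, "zscore") <- zscore
  out
}

#' Pearson correlation distance between voxel rows
#'
#' `S1(i, j) = 1 - r(i, j)` with `r` the Pearson correlation of rows `i` and
#' `j`, the functional-connectivity distance used throughout the pipeline.
#' Values lie in `[0, 2]` with a zero diagonal. Rows with zero variance have
#' undefined correlation; they are excluded with a warning and reported in
#' the `excluded` attribute.
#'
#' @param m Voxel x observation matrix (>= 2 columns).
#' @return Symmetric distance matrix over the retained voxels, with
#'   attributes `excluded` (indices of dropped zero-variance rows, possibly
#'   empty) and `kept` (row indices retained).
#' @export
correlation_distance <- function(m) {
  if (ncol(m) < 2L) stop("need at least 2 columns", call. = FALSE)
  v <- apply(m, 1L, stats::var)
  bad <- which(v == 0 | !is.finite(v))
  kept <- setdiff(seq_len(nrow(m)), bad)
  if (length(bad) > 0L) {
    warning("excluding ", length(bad),
            " zero-variance voxel(s) with undefined correlation: ",
            paste(utils::head(bad, 5L), collapse = ", "),
            if (length(bad) > 5L) ", ..." else "", call. = FALSE)
  }
  if (length(kept) < 2L) stop("fewer than 2 voxels with nonzero variance", call. = FALSE)
  r <- stats::cor(t(m[kept, , drop = FALSE]))
  d <- 1 - r
  diag(d) <- 0
  d <- (d + t(d)) / 2
  attr(d, "excluded") <- bad
  attr(d, "kept") <- kept
  d
}

#' Top-fraction nearest-neighbour graph
#'
#' For every voxel, marks its `k = round(fraction * (n - 1))` most correlated
#' other voxels (smallest `1 - r` distances; the voxel itself is excluded).
#' Ties at the k-th distance are broken toward the lower voxel index, making
#' the graph deterministic.
#'
#' @param distance_matrix Square distance matrix, e.g. from
#'   [correlation_distance()].
#' @param fraction Neighbourhood size as a fraction of the other voxels
#'   (default 0.05, the nearest 5%).
#' @return `n x n` binary (0/1) matrix; row `i` indicates voxel `i`'s
#'   neighbour set and sums to `k` exactly. Attribute `k` records the set
#'   size.
#' @export
top_fraction_neighbors <- function(distance_matrix, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)", call. = FALSE)
  n <- nrow(distance_matrix)
  k <- round(fraction * (n - 1))
  if (k < 1) {
    stop("fraction ", fraction, " of ", n - 1,
         " other voxels rounds to an empty neighbour set", call. = FALSE)
  }
  g <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    d <- distance_matrix[i, ]
    d[i] <- Inf
    ord <- order(d, seq_len(n))    # secondary key: lower index wins ties
    g[i, ord[seq_len(k)]] <- 1L
  }
  attr(g, "k") <- k
  g
}
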