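#' Jaccard distance between two binary neighbour sets
#'
#' Fraction of elements that differ between the sets, relative to their
#' union: `#[(v != w) & (v | w)] / #[v | w]`. 0 for identical sets, 1 for
#' disjoint non-empty sets. Undefined when both vectors are all zero; this
#' is signalled as an error of class `wpfc_jaccard_undefined`.
#'
#' @param v,w Binary (0/1 or logical) vectors of equal length.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' jaccard_distance(c(1, 1, 0), c(1, 0, 1))  # 2/3
jaccard_distance <- function(v, w) {
  if (length(v) != length(w)) stop("`v` and `w` must have equal length", call. = FALSE)
  v <- as.logical(v); w <- as.logical(w)
  un <- sum(v | w)
  if (un == 0L) {
    stop(structure(
      class = c("wpfc_jaccard_undefined", "error", "condition"),
      list(message = "Jaccard distance undefined: both sets are empty",
           call = sys.call(-1))
    ))
  }
  sum(v != w) / un
}

#' Default wideband packet selection
#'
#' The six subbands spanning ~12-194 mHz whose inverse transform defines the
#' wideband reference signal: D6P1, D5P1, D4P1, D5P4, D5P5, D4P3.
#'
#' @return Character vector of six packet addresses.
#' @export
default_wideband_packets <- function() {
  c("D6P1", "D5P1", "D4P1", "D5P4", "D5P5", "D4P3")
}

#' Per-subject neighbour graphs from one packet's coefficients
#'
#' Decomposes each subject's voxel series, takes the addressed packet's
#' coefficients, and builds the top-`fraction` correlation neighbour graph.
#'
#' @param datasets List of `bold_dataset` objects (or voxel x time
#'   matrices, in which case `tr_seconds` must be given).
#' @param address Packet address (`"DdPp"` or `packet_address`).
#' @param fraction Neighbourhood fraction (default 0.05).
#' @param max_depth Decomposition depth (default 6).
#' @param filters Filter pair (default db7).
#' @param tr_seconds Sampling interval when `datasets` are bare matrices.
#' @return List of binary neighbour-graph matrices, one per subject.
#' @export
packet_neighbor_graphs <- function(datasets, address, fraction = 0.05,
                                   max_depth = 6L, filters = db7_filters(),
                                   tr_seconds = NULL) {
  lapply(datasets, function(ds) {
    x <- if (inherits(ds, "bold_dataset")) ds$data else ds
    tr <- if (inherits(ds, "bold_dataset")) ds$tr_seconds else tr_seconds
    if (is.null(tr)) stop("`tr_seconds` required for bare matrices", call. = FALSE)
    tree <- wpt_decompose(x, fs = 1 / tr, max_depth = max_depth,
                          filters = filters)
    top_fraction_neighbors(
      correlation_distance(packet_coefficients(tree, address)),
      fraction = fraction
    )
  })
}

#' Wideband reference neighbour graphs
#'
#' Per subject: inverse wavelet packet transform keeping only the selected
#' packets (all other coefficients zeroed), then correlation distance over
#' the reconstructed voxel series, then the top-`fraction` neighbour graph.
#' This is the baseline each subband graph is compared against.
#'
#' @inheritParams packet_neighbor_graphs
#' @param selected_packets Character vector of packet addresses (default the
#'   six-packet set of [default_wideband_packets()]); must be
#'   non-overlapping.
#' @return List of binary neighbour-graph matrices, one per subject.
#' @export
build_wideband_reference <- function(datasets,
                                     selected_packets = default_wideband_packets(),
                                     fraction = 0.05, max_depth = 6L,
                                     filters = db7_filters(),
                                     tr_seconds = NULL) {
  lapply(datasets, function(ds) {
    x <- if (inherits(ds, "bold_dataset")) ds$data else ds
    tr <- if (inherits(ds, "bold_dataset")) ds$tr_seconds else tr_seconds
    if (is.null(tr)) stop("`tr_seconds` required for bare matrices", call. = FALSE)
    tree <- wpt_decompose(x, fs = 1 / tr, max_depth = max_depth,
                          filters = filters)
    wide <- wpt_reconstruct(tree, selected_packets)
    top_fraction_neighbors(correlation_distance(wide), fraction = fraction)
  })
}

#' Voxelwise Jaccard map between subband and reference graphs
#'
#' For every voxel and subject, the Jaccard distance between the voxel's
#' neighbour set in the subband graph and in the reference graph; reported
#' as the mean and standard deviation across subjects.
#'
#' @param packet_graphs,reference_graphs Lists (one element per subject) of
#'   binary neighbour-graph matrices over the same voxels.
#' @return Data frame with columns `voxel`, `mean_jd`, `sd_jd` (`sd_jd` is 0
#'   with a single subject).
#' @export
voxelwise_jaccard_map <- function(packet_graphs, reference_graphs) {
  ns <- length(packet_graphs)
  if (ns != length(reference_graphs)) {
    stop("subject count mismatch: ", ns, " packet vs ",
         length(reference_graphs), " reference graphs", call. = FALSE)
  }
  if (ns < 1L) stop("need at least one subject", call. = FALSE)
  nv <- nrow(packet_graphs[[1]])
  jd <- matrix(NA_real_, nv, ns)
  for (s in seq_len(ns)) {
    pg <- packet_graphs[[s]]; rg <- reference_graphs[[s]]
    if (!all(dim(pg) == c(nv, nv)) || !all(dim(rg) == c(nv, nv))) {
      stop("graphs must share the voxel set", call. = FALSE)
    }
    for (v in seq_len(nv)) jd[v, s] <- jaccard_distance(pg[v, ], rg[v, ])
  }
  data.frame(
    voxel = seq_len(nv),
    mean_jd = rowMeans(jd),
    sd_jd = if (ns == 1L) rep(0, nv) else apply(jd, 1L, stats::sd)
  )
}
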