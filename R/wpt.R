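#' @title Wavelet packet addressing
#' @description A packet is addressed by its depth `d` and its
#'   frequency-ordered position `p` in `0 .. 2^d - 1`, printed `"DdPp"`:
#'   `D0P0` is the broadband signal, and at fixed depth positions index
#'   bands of width `(fs/2)/2^d` in increasing frequency.
#' @param depth Non-negative integer tree depth.
#' @param position Integer position, `0 <= position <= 2^depth - 1`,
#'   frequency-ordered.
#' @return A `packet_address` object.
#' @export
#' @examples
#' packet_address(6, 1)             # D6P1
#' parse_packet_address("D5P4")
packet_address <- function(depth, position) {
  depth <- as.integer(depth); position <- as.integer(position)
  if (is.na(depth) || depth < 0L) stop("`depth` must be a non-negative integer", call. = FALSE)
  if (is.na(position) || position < 0L || position > 2^depth - 1) {
    stop("`position` must lie in 0 .. 2^depth - 1 (got p=", position,
         " at depth ", depth, ")", call. = FALSE)
  }
  structure(list(depth = depth, position = position), class = "packet_address")
}

#' @rdname packet_address
#' @param x A `packet_address`, or a string of the form `"D5P1"`.
#' @export
parse_packet_address <- function(x) {
  if (inherits(x, "packet_address")) return(x)
  if (!is.character(x) || length(x) != 1L || !grepl("^D[0-9]+P[0-9]+$", x)) {
    stop("packet address must look like \"D5P1\"", call. = FALSE)
  }
  m <- regmatches(x, regexec("^D([0-9]+)P([0-9]+)$", x))[[1]]
  packet_address(as.integer(m[2]), as.integer(m[3]))
}

#' @export
format.packet_address <- function(x, ...) sprintf("D%dP%d", x$depth, x$position)

#' @export
print.packet_address <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.packet_address <- function(x, ...) format(x)

# normalize a vector/list of addresses to a list of packet_address
as_address_list <- function(keep) {
  if (inherits(keep, "packet_address")) keep <- list(keep)
  lapply(keep, parse_packet_address)
}

#' Frequency (sequency) ordering of wavelet packet positions
#'
#' The natural filter-bank ordering of packet nodes (low child first,
#' recursively) is band-shuffled: because downsampling mirrors the spectrum
#' of every high-pass branch, the node reached by the natural path `p`
#' occupies frequency band `gray(p)`. This returns, for a depth, the natural
#' positions listed in increasing frequency order, i.e. the binary-reflected
#' Gray code of `0 .. 2^depth - 1`; element `i + 1` is the natural position
#' holding frequency band `i`.
#'
#' @param depth Non-negative integer.
#' @return Integer vector of length `2^depth`.
#' @export
#' @examples
#' frequency_order_positions(2)  # 0 1 3 2
#' frequency_order_positions(3)  # 0 1 3 2 6 7 5 4
frequency_order_positions <- function(depth) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth < 0L) stop("`depth` must be a non-negative integer", call. = FALSE)
  p <- 0:(2^depth - 1)
  bitwXor(p, bitwShiftR(p, 1L))
}

# natural position storing frequency-ordered position p at given depth
freq_to_natural <- function(depth, position) {
  bitwXor(position, bitwShiftR(position, 1L))
}

#' Analytic passband of a wavelet packet
#'
#' For a frequency-ordered packet at depth `d`, position `p`, the nominal
#' passband is `[p (fs/2)/2^d, (p+1)(fs/2)/2^d]` Hz. Edges are nominal:
#' finite filters leak energy across them.
#'
#' @param address A `packet_address` or `"DdPp"` string.
#' @param fs Sampling frequency in Hz (`1/TR` for fMRI).
#' @return Numeric `c(lo, hi)` in Hz.
#' @export
#' @examples
#' packet_passband("D6P1", fs = 1 / 0.645)  # ~0.0121 0.0242 Hz (12-24 mHz)
packet_passband <- function(address, fs) {
  a <- parse_packet_address(address)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  w <- (fs / 2) / 2^a$depth
  c(a$position * w, (a$position + 1) * w)
}

# ---- periodized analysis/synthesis matrices, cached by (length, filter) ----

.wpfc_amat_cache <- new.env(parent = emptyenv())

analysis_matrix <- function(n, f, tag) {
  key <- paste0(tag, "_", n)
  hit <- .wpfc_amat_cache[[key]]
  if (!is.null(hit)) return(hit)
  L <- length(f)
  M <- matrix(0, n / 2, n)
  for (k in 0:(n / 2 - 1)) {
    for (m in 0:(L - 1)) {
      j <- (m + 2 * k) %% n + 1
      M[k + 1, j] <- M[k + 1, j] + f[m + 1]
    }
  }
  .wpfc_amat_cache[[key]] <- M
  M
}

# one analysis step for row-signals X; odd lengths are extended by repeating
# the last sample (ceil-halving), which keeps the even-length step orthogonal
split_node <- function(X, filters) {
  n <- ncol(X)
  if (n %% 2 == 1) {
    X <- cbind(X, X[, n, drop = FALSE])
    n <- n + 1
  }
  tagbase <- paste0("db", filters$n_moments)
  list(
    low  = X %*% t(analysis_matrix(n, filters$lowpass,  paste0(tagbase, "L"))),
    high = X %*% t(analysis_matrix(n, filters$highpass, paste0(tagbase, "H")))
  )
}

merge_node <- function(low, high, filters, orig_len) {
  n <- 2 * ncol(low)
  tagbase <- paste0("db", filters$n_moments)
  X <- low %*% analysis_matrix(n, filters$lowpass, paste0(tagbase, "L")) +
    high %*% analysis_matrix(n, filters$highpass, paste0(tagbase, "H"))
  X[, seq_len(orig_len), drop = FALSE]
}

#' Full wavelet packet decomposition
#'
#' Applies the two-channel filter bank recursively to every node through
#' `max_depth` levels, producing all `2^(d+1) - 1` subband nodes for depths
#' `0 .. max_depth` (127 at the default depth 6). The transform is
#' periodized: filters wrap circularly, so each even-length split is an
#' orthogonal map and reconstruction is exact. Odd-length nodes are extended
#' by one repeated sample before splitting (ceil-halving per level).
#'
#' @param x Numeric vector (one series) or matrix with one series per row
#'   (voxels x time); rows are transformed independently.
#' @param fs Sampling frequency in Hz, stored for passband queries.
#' @param max_depth Decomposition depth (default 6).
#' @param filters A `filter_pair` (default [db7_filters()]).
#' @return A `packet_tree`.
#' @export
#' @examples
#' tree <- wpt_decompose(rnorm(256), fs = 1 / 0.645, max_depth = 3)
#' n_packets(tree)  # 15
#' dim(packet_coefficients(tree, "D3P2"))
wpt_decompose <- function(x, fs, max_depth = 6L, filters = db7_filters()) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric vector or matrix", call. = FALSE)
  max_depth <- as.integer(max_depth)
  if (max_depth < 0L) stop("`max_depth` must be >= 0", call. = FALSE)
  if (ncol(x) < 2^max_depth) {
    stop("series length ", ncol(x), " is shorter than 2^max_depth = ",
         2^max_depth, "; supply at least 2^max_depth samples", call. = FALSE)
  }
  nodes <- vector("list", max_depth + 1L)
  nodes[[1]] <- list(x)
  if (max_depth > 0L) {
    for (d in seq_len(max_depth)) {
      prev <- nodes[[d]]
      cur <- vector("list", 2L * length(prev))
      for (p in seq_along(prev)) {
        sp <- split_node(prev[[p]], filters)
        cur[[2 * p - 1]] <- sp$low
        cur[[2 * p]] <- sp$high
      }
      nodes[[d + 1L]] <- cur
    }
  }
  structure(
    list(nodes = nodes, max_depth = max_depth, fs = fs,
         n_time = ncol(x), n_signals = nrow(x), filters = filters),
    class = "packet_tree"
  )
}

#' @rdname wpt_decompose
#' @param tree A `packet_tree`.
#' @export
n_packets <- function(tree) {
  stopifnot(inherits(tree, "packet_tree"))
  sum(lengths(tree$nodes))
}

#' Coefficients of one packet, frequency-ordered addressing
#'
#' @param tree A `packet_tree`.
#' @param address `packet_address` or `"DdPp"` string (frequency-ordered
#'   position).
#' @return Matrix of coefficients, one row per input series.
#' @export
packet_coefficients <- function(tree, address) {
  stopifnot(inherits(tree, "packet_tree"))
  a <- parse_packet_address(address)
  if (a$depth > tree$max_depth) {
    stop("tree was decomposed to depth ", tree$max_depth, call. = FALSE)
  }
  tree$nodes[[a$depth + 1L]][[freq_to_natural(a$depth, a$position) + 1L]]
}

#' @export
print.packet_tree <- function(x, ...) {
  cat("<packet_tree> depth ", x$max_depth, ", ", n_packets(x), " nodes, ",
      x$n_signals, " series x ", x$n_time, " samples, fs = ",
      signif(x$fs, 5), " Hz\n", sep = "")
  invisible(x)
}

#' Inverse wavelet packet transform from a packet subset
#'
#' Rebuilds the time series keeping only the listed packets; coefficients of
#' every other node are set to zero before inverting. Kept packets must not
#' overlap (no address may be an ancestor of another), since overlapping
#' nodes represent the same signal content twice.
#'
#' @param tree A `packet_tree` from [wpt_decompose()].
#' @param keep Character vector of `"DdPp"` strings, or list of
#'   `packet_address` objects; may be empty (gives the zero series).
#' @return Matrix (series x time) matching the decomposed input; a kept set
#'   covering a full depth reproduces the input to machine precision.
#' @export
wpt_reconstruct <- function(tree, keep) {
  stopifnot(inherits(tree, "packet_tree"))
  keep <- as_address_list(keep)
  # natural-order (depth, position) pairs
  nat <- lapply(keep, function(a) {
    if (a$depth > tree$max_depth) {
      stop("address ", format(a), " exceeds tree depth ", tree$max_depth, call. = FALSE)
    }
    c(a$depth, freq_to_natural(a$depth, a$position))
  })
  if (length(nat) > 1L) {
    key <- vapply(nat, function(dp) paste0(dp[1], ":", dp[2]), "")
    if (anyDuplicated(key)) stop("duplicate packet addresses in `keep`", call. = FALSE)
    for (i in seq_along(nat)) {
      for (j in seq_along(nat)) {
        di <- nat[[i]][1]; dj <- nat[[j]][1]
        if (di < dj && nat[[j]][2] %/% 2^(dj - di) == nat[[i]][2]) {
          stop("overlapping packets: ", format(keep[[i]]), " is an ancestor of ",
               format(keep[[j]]), call. = FALSE)
        }
      }
    }
  }
  # zero-filled skeleton with the tree's node shapes
  acc <- lapply(tree$nodes, function(lev) {
    lapply(lev, function(m) matrix(0, nrow(m), ncol(m)))
  })
  for (dp in nat) {
    acc[[dp[1] + 1L]][[dp[2] + 1L]] <- tree$nodes[[dp[1] + 1L]][[dp[2] + 1L]]
  }
  if (tree$max_depth > 0L) {
    for (d in tree$max_depth:1L) {
      for (p in seq_along(acc[[d]])) {
        up <- merge_node(acc[[d + 1L]][[2 * p - 1]], acc[[d + 1L]][[2 * p]],
                         tree$filters, ncol(acc[[d]][[p]]))
        acc[[d]][[p]] <- acc[[d]][[p]] + up
      }
    }
  }
  acc[[1]][[1]]
}
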