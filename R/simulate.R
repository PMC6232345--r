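#' Simulation configuration for synthetic multi-subject BOLD-like data
#'
#' Bundles and validates every knob of the generator. The defaults mirror the
#' acquisition the pipeline is designed around: 900 volumes at TR = 0.645 s
#' (multiband resting-state fMRI), voxelwise 1/f^gamma background noise with
#' gamma in the 0.5-1 range reported for BOLD, and one or more "planted
#' layers": parcellations of the voxels whose clusters share a band-limited
#' signal confined to a passband, so that frequency-resolved connectivity has
#' a known ground truth.
#'
#' @param n_voxels Number of masked voxels.
#' @param n_subjects Number of subjects; subjects share partitions but get
#'   independent noise and signal realizations.
#' @param n_timepoints Samples per series (default 900).
#' @param tr_seconds Sampling interval in seconds (default 0.645).
#' @param gamma Spectral exponent of the 1/f^gamma background (>= 0).
#' @param planted_layers List of layers; each layer is a list with elements
#'   `passband` (`c(lo, hi)` Hz, inside `[0, 1/(2 tr)]`), `partition`
#'   (integer labels, one per voxel), and `amplitude` (cluster-signal SD
#'   relative to the unit-SD noise, >= 0).
#' @param mask_fraction Fraction of a nominal volume retained by
#'   [generate_mask()] (used when writing volumes; default 0.5).
#' @param seed Integer seed; all randomness is derived from it.
#' @param max_elements Guard: error if `n_voxels * n_timepoints` exceeds this.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(n_voxels, n_subjects, n_timepoints = 900L,
                              tr_seconds = 0.645, gamma = 0.8,
                              planted_layers = list(), mask_fraction = 0.5,
                              seed = 1L, max_elements = 5e7) {
  n_voxels <- as.integer(n_voxels); n_subjects <- as.integer(n_subjects)
  n_timepoints <- as.integer(n_timepoints)
  if (n_voxels < 2L) stop("`n_voxels` must be >= 2", call. = FALSE)
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1", call. = FALSE)
  if (n_timepoints < 16L) stop("`n_timepoints` must be >= 16", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be finite and >= 0", call. = FALSE)
  if (tr_seconds <= 0) stop("`tr_seconds` must be positive", call. = FALSE)
  if (mask_fraction <= 0 || mask_fraction > 1) stop("`mask_fraction` must be in (0, 1]", call. = FALSE)
  if (as.double(n_voxels) * n_timepoints > max_elements) {
    stop("n_voxels * n_timepoints = ", as.double(n_voxels) * n_timepoints,
         " exceeds the memory guard (", max_elements, ")", call. = FALSE)
  }
  nyquist <- 1 / (2 * tr_seconds)
  for (i in seq_along(planted_layers)) {
    ly <- planted_layers[[i]]
    if (!all(c("passband", "partition", "amplitude") %in% names(ly))) {
      stop("layer ", i, " needs `passband`, `partition`, `amplitude`", call. = FALSE)
    }
    pb <- ly$passband
    if (length(pb) != 2L || pb[1] >= pb[2]) {
      stop("layer ", i, ": degenerate passband (need lo < hi)", call. = FALSE)
    }
    if (pb[1] < 0 || pb[2] > nyquist + 1e-12) {
      stop("layer ", i, ": passband outside [0, ", signif(nyquist, 4), "] Hz", call. = FALSE)
    }
    if (length(ly$partition) != n_voxels || anyNA(ly$partition)) {
      stop("layer ", i, ": partition must label every voxel", call. = FALSE)
    }
    if (!is.finite(ly$amplitude) || ly$amplitude < 0) {
      stop("layer ", i, ": amplitude must be >= 0", call. = FALSE)
    }
  }
  structure(
    list(n_voxels = n_voxels, n_subjects = n_subjects,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds, gamma = gamma,
         planted_layers = planted_layers, mask_fraction = mask_fraction,
         seed = as.integer(seed), max_elements = max_elements),
    class = "simulation_config"
  )
}

# spectral shaping weights for 1/f^(gamma/2) amplitude per FFT bin; DC zeroed
one_over_f_weights <- function(n, tr_seconds, gamma) {
  k <- 0:(n - 1)
  kk <- pmin(k, n - k)            # fold negative frequencies
  f <- kk / (n * tr_seconds)
  w <- c(0, f[-1]^(-gamma / 2))
  w
}

#' Generate 1/f^gamma background series
#'
#' Spectral shaping of Gaussian white noise: the FFT of a white series is
#' multiplied by `f^(-gamma/2)` (the DC bin is zeroed) and inverted, giving a
#' zero-mean series whose expected periodogram follows `S(f) ~ 1/f^gamma`
#' exactly by construction. Output is scaled to unit standard deviation.
#'
#' @param n_timepoints Series length (>= 16).
#' @param tr_seconds Sampling interval, seconds.
#' @param gamma Spectral exponent (finite, >= 0); `gamma = 0` is white noise.
#' @param seed Integer seed; the same seed gives the identical series.
#' @param n_series Number of independent series (rows of the result).
#' @return Numeric matrix `n_series x n_timepoints` (a vector if
#'   `n_series = 1`).
#' @export
generate_one_over_f_series <- function(n_timepoints, tr_seconds, gamma, seed,
                                       n_series = 1L) {
  if (!is.finite(gamma) || gamma < 0) stop("`gamma` must be finite and >= 0", call. = FALSE)
  n <- as.integer(n_timepoints)
  if (n < 16L) stop("`n_timepoints` must be >= 16", call. = FALSE)
  w <- one_over_f_weights(n, tr_seconds, gamma)
  white <- with_seed(seed, matrix(stats::rnorm(n * n_series), nrow = n))
  sh <- stats::mvfft(white) * w
  x <- Re(stats::mvfft(sh, inverse = TRUE)) / n
  x <- sweep(x, 2L, apply(x, 2L, stats::sd), "/")
  out <- t(x)
  if (n_series == 1L) drop(out) else out
}

#' Generate band-limited shared cluster signals
#'
#' One independent series per cluster label, built by hard FFT-bin masking of
#' white noise: all bins whose frequency falls outside `passband` (and the DC
#' bin) are zeroed before inverting, so essentially all spectral energy lies
#' inside the band. Each series is scaled to unit standard deviation.
#'
#' @param partition Integer cluster labels (defines the set of clusters).
#' @param passband `c(lo, hi)` in Hz, `lo < hi`, inside `[0, Nyquist]`.
#' @param n_timepoints Series length.
#' @param tr_seconds Sampling interval, seconds.
#' @param seed Integer seed.
#' @return List with `labels` (sorted unique labels) and `signals`
#'   (matrix, one row per label, `n_timepoints` columns).
#' @export
generate_band_limited_cluster_signals <- function(partition, passband,
                                                  n_timepoints, tr_seconds,
                                                  seed) {
  if (length(partition) == 0L) stop("`partition` must be non-empty", call. = FALSE)
  if (length(passband) != 2L || passband[1] >= passband[2]) {
    stop("degenerate passband: need lo < hi", call. = FALSE)
  }
  nyq <- 1 / (2 * tr_seconds)
  if (passband[1] < 0 || passband[2] > nyq + 1e-12) {
    stop("passband outside [0, ", signif(nyq, 4), "] Hz", call. = FALSE)
  }
  n <- as.integer(n_timepoints)
  labels <- sort(unique(partition))
  nc <- length(labels)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) / (n * tr_seconds)
  keep <- as.numeric(f >= passband[1] & f <= passband[2])
  keep[1] <- 0                                  # zero-mean
  if (sum(keep) == 0) stop("passband contains no FFT bin at this length/TR", call. = FALSE)
  white <- with_seed(seed, matrix(stats::rnorm(n * nc), nrow = n))
  sh <- stats::mvfft(white) * keep
  x <- Re(stats::mvfft(sh, inverse = TRUE)) / n
  x <- sweep(x, 2L, apply(x, 2L, stats::sd), "/")
  list(labels = labels, signals = t(x))
}

#' Generate a gray-matter-like blob mask
#'
#' Thresholds a smoothed Gaussian random field, giving irregular contiguous
#' blobs reminiscent of a tissue mask without any anatomy. Exactly
#' `round(mask_fraction * prod(volume_shape))` voxels are retained (the
#' highest-valued cells of the smoothed field). The voxel order used
#' throughout the package is the column-major order of `TRUE` cells,
#' i.e. `which(mask)`.
#'
#' @param volume_shape Integer vector of array dimensions, e.g. `c(10,10,10)`.
#' @param mask_fraction Fraction of voxels retained, in (0, 1].
#' @param seed Integer seed.
#' @param smooth_sd Gaussian smoothing SD in voxels (default 1.5).
#' @return Logical array of dimension `volume_shape`.
#' @export
generate_mask <- function(volume_shape, mask_fraction, seed, smooth_sd = 1.5) {
  if (mask_fraction <= 0 || mask_fraction > 1) {
    stop("`mask_fraction` must be in (0, 1]", call. = FALSE)
  }
  nv <- prod(volume_shape)
  n_keep <- round(mask_fraction * nv)
  if (n_keep < 1) stop("mask would be empty", call. = FALSE)
  field <- with_seed(seed, array(stats::rnorm(nv), dim = volume_shape))
  # separable Gaussian smoothing with edge replication
  r <- max(1L, ceiling(3 * smooth_sd))
  kern <- stats::dnorm(-r:r, sd = smooth_sd)
  kern <- kern / sum(kern)
  smooth_axis <- function(a, axis) {
    perm <- c(axis, setdiff(seq_along(dim(a)), axis))
    b <- aperm(a, perm)
    d <- dim(b)
    m <- matrix(b, nrow = d[1])
    mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(nrow(m), r), , drop = FALSE])
    sm <- apply(mp, 2L, function(col) stats::filter(col, kern, sides = 2L))
    sm <- sm[(r + 1):(r + d[1]), , drop = FALSE]
    array(aperm(array(sm, dim = d), order(perm)), dim = dim(a))
  }
  for (ax in seq_along(volume_shape)) field <- smooth_axis(field, ax)
  thr <- sort(as.vector(field), decreasing = TRUE)[n_keep]
  mask <- field >= thr
  # exact count under ties: keep the first n_keep in column-major order
  if (sum(mask) > n_keep) {
    idx <- which(mask)
    mask[idx[seq(n_keep + 1L, length(idx))]] <- FALSE
  }
  mask
}

#' Synthesize a multi-subject dataset with planted spectral network structure
#'
#' Per subject and voxel, the series is the sum over planted layers of
#' `amplitude * (the band-limited signal shared by that voxel's cluster)`
#' plus unit-SD 1/f^gamma noise, then z-scored per voxel (mirroring the
#' implicit normalization of correlation analysis). Subjects share the
#' ground-truth partitions but receive independent noise and signal
#' realizations, matching a group-concatenation design.
#'
#' @param config A [simulation_config()].
#' @return List with `datasets` (one `bold_dataset` per subject: a list with
#'   `data` voxel x time matrix, `tr_seconds`, `subject`) and `ground_truth`
#'   (layers with passbands/partitions/amplitudes, per-subject realized
#'   cluster signals, config echo).
#' @export
synthesize_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nv <- config$n_voxels; nt <- config$n_timepoints
  datasets <- vector("list", config$n_subjects)
  realized <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    noise <- generate_one_over_f_series(
      nt, config$tr_seconds, config$gamma,
      seed = derive_seed(config$seed, 1L, s), n_series = nv
    )
    if (nv == 1L) noise <- matrix(noise, nrow = 1L)
    x <- noise
    sigs <- list()
    for (li in seq_along(config$planted_layers)) {
      ly <- config$planted_layers[[li]]
      cs <- generate_band_limited_cluster_signals(
        ly$partition, ly$passband, nt, config$tr_seconds,
        seed = derive_seed(config$seed, 2L, s, li)
      )
      rows <- match(ly$partition, cs$labels)
      x <- x + ly$amplitude * cs$signals[rows, , drop = FALSE]
      sigs[[li]] <- cs
    }
    mu <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    x <- (x - mu) / sdv
    datasets[[s]] <- structure(
      list(data = x, tr_seconds = config$tr_seconds, subject = s),
      class = "bold_dataset"
    )
    realized[[s]] <- sigs
  }
  ground_truth <- list(
    layers = lapply(config$planted_layers, function(ly) {
      ly[c("passband", "partition", "amplitude")]
    }),
    signals = realized,
    config = config
  )
  list(datasets = datasets, ground_truth = ground_truth)
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat("<bold_dataset> subject ", x$subject, ": ", nrow(x$data), " voxels x ",
      ncol(x$data), " timepoints, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Write / read a synthesized dataset as NIfTI volumes plus ground truth
#'
#' Voxels are placed into the mask in `which(mask)` (column-major) order,
#' producing one 4-D volume per subject, a mask volume, and a JSON ground
#' truth (labels, passbands, seed, config echo).
#'
#' @param sim Result of [synthesize_dataset()].
#' @param mask Logical array from [generate_mask()] with
#'   `sum(mask) == n_voxels`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset_nifti <- function(sim, mask, dir) {
  if (sum(mask) != nrow(sim$datasets[[1]]$data)) {
    stop("mask voxel count (", sum(mask), ") must equal n_voxels (",
         nrow(sim$datasets[[1]]$data), ")", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- sim$datasets[[1]]$tr_seconds
  idx <- which(mask)
  for (s in seq_along(sim$datasets)) {
    d <- sim$datasets[[s]]$data
    vol <- array(0, dim = c(dim(mask), ncol(d)))
    nvox <- prod(dim(mask))
    for (t in seq_len(ncol(d))) vol[idx + (t - 1) * nvox] <- d[, t]
    img <- RNifti::asNifti(vol, pixdim = c(1, 1, 1, tr))
    RNifti::writeNifti(img, file.path(dir, sprintf("sub-%02d_bold.nii.gz", s)))
  }
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(mask), dim = dim(mask))),
                     file.path(dir, "mask.nii.gz"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(
      n_subjects = length(sim$datasets),
      tr_seconds = tr,
      seed = gt$config$seed,
      gamma = gt$config$gamma,
      layers = lapply(gt$layers, function(ly) {
        list(passband_hz = ly$passband, amplitude = ly$amplitude,
             partition = as.integer(ly$partition))
      })
    ),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' @rdname write_dataset_nifti
#' @export
read_dataset_nifti <- function(dir) {
  mask_img <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  mask <- array(as.logical(mask_img > 0), dim = dim(mask_img))
  idx <- which(mask)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^sub-.*_bold\\.nii\\.gz$",
                           full.names = TRUE))
  datasets <- lapply(seq_along(files), function(s) {
    vol <- RNifti::readNifti(files[s])
    nt <- dim(vol)[4]
    nvox <- prod(dim(mask))
    d <- vapply(seq_len(nt), function(t) vol[idx + (t - 1) * nvox],
                numeric(length(idx)))
    structure(list(data = d, tr_seconds = gt$tr_seconds, subject = s),
              class = "bold_dataset")
  })
  list(datasets = datasets, mask = mask, ground_truth = gt)
}
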