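#' Run the full multispectral connectivity pipeline
#'
#' Orchestrates simulate -> decompose -> group connectivity -> cluster ->
#' VI comparison -> voxelwise Jaccard, with every parameter and output path
#' recorded in a run manifest. All randomness derives from the seed inside
#' `config`, so a config re-run reproduces its outputs bit-identically.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory for CSV/JSON artifacts; `NULL` keeps
#'   results in memory only.
#' @param analysis_packets Packet addresses to analyse (default: the six
#'   wideband packets of [default_wideband_packets()]).
#' @param max_depth Decomposition depth (default 6).
#' @param fraction Neighbour fraction for graphs (default 0.05).
#' @param zscore Z-score subject blocks before group concatenation.
#' @param n_clusters Prune each subband dendrogram to this many clusters;
#'   if `NULL`, prune by `inconsistency_threshold` instead.
#' @param inconsistency_threshold Threshold on global inconsistency used
#'   when `n_clusters` is `NULL` (default 1).
#' @param g Inconsistency window (integer or `"global"`) for
#'   threshold-based pruning.
#' @param wideband_packets Packet set defining the wideband reference.
#' @param designated Packets designated for the fine-global spectral
#'   meta-clustering (default: the analysis packets with passband entirely
#'   below 0.1 Hz).
#' @return A list with `manifest`, `sim`, `partitions`, `vi`,
#'   `meta_coarse`, `meta_fine`, and `jaccard_maps`, invisibly writing CSVs
#'   and a `manifest.json` under `out_dir` when given.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         analysis_packets = default_wideband_packets(),
                         max_depth = 6L, fraction = 0.05, zscore = TRUE,
                         n_clusters = NULL, inconsistency_threshold = 1,
                         g = "global",
                         wideband_packets = default_wideband_packets(),
                         designated = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  t0 <- Sys.time()
  fs <- 1 / config$tr_seconds
  log_stage <- function(...) message("[wpfc] ", ...)

  log_stage("simulate: ", config$n_subjects, " subjects x ", config$n_voxels,
            " voxels x ", config$n_timepoints, " timepoints")
  sim <- synthesize_dataset(config)

  log_stage("decompose: depth ", max_depth, ", ", length(analysis_packets),
            " analysis packets")
  trees <- lapply(sim$datasets, function(ds) {
    wpt_decompose(ds$data, fs = fs, max_depth = max_depth)
  })

  log_stage("connectivity + clustering per packet")
  partitions <- list()
  for (pk in analysis_packets) {
    grp <- concatenate_group(
      lapply(trees, packet_coefficients, address = pk), zscore = zscore
    )
    dm <- correlation_distance(grp)
    tr <- average_linkage(dm)
    partitions[[pk]] <- if (!is.null(n_clusters)) {
      prune_to_k(tr, n_clusters)
    } else {
      prune_by_inconsistency(tr, inconsistency(tr, g = g),
                             inconsistency_threshold)
    }
  }

  log_stage("variation of information + spectral meta-clustering")
  vi <- vi_matrix(partitions)
  if (is.null(designated)) {
    lows <- vapply(analysis_packets, function(pk) {
      packet_passband(pk, fs)[2] <= 0.1
    }, logical(1))
    designated <- analysis_packets[lows]
    if (length(designated) == 0L) designated <- analysis_packets
  }
  meta_coarse <- cluster_spectra(vi, mode = "coarse-local")
  meta_fine <- cluster_spectra(vi, mode = "fine-global",
                               designated = designated)

  log_stage("voxelwise Jaccard vs wideband reference")
  reference <- build_wideband_reference(sim$datasets,
                                        selected_packets = wideband_packets,
                                        fraction = fraction,
                                        max_depth = max_depth)
  jaccard_maps <- list()
  for (pk in analysis_packets) {
    graphs <- lapply(trees, function(tree) {
      top_fraction_neighbors(
        correlation_distance(packet_coefficients(tree, pk)),
        fraction = fraction
      )
    })
    jaccard_maps[[pk]] <- voxelwise_jaccard_map(graphs, reference)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("wpfc")),
    seed = config$seed,
    parameters = list(
      n_voxels = config$n_voxels, n_subjects = config$n_subjects,
      n_timepoints = config$n_timepoints, tr_seconds = config$tr_seconds,
      gamma = config$gamma, n_layers = length(config$planted_layers),
      max_depth = max_depth, fraction = fraction, zscore = zscore,
      n_clusters = n_clusters, inconsistency_threshold = inconsistency_threshold,
      g = as.character(g), analysis_packets = analysis_packets,
      wideband_packets = wideband_packets, designated = designated
    ),
    counts = list(
      n_packets_total = 2^(max_depth + 1) - 1,
      clusters_per_packet = vapply(partitions, function(p) length(unique(p)), 0)
    ),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    part_df <- data.frame(voxel = seq_len(config$n_voxels),
                          lapply(partitions, as.integer),
                          check.names = FALSE)
    utils::write.csv(part_df, file.path(out_dir, "partitions.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(vi), file.path(out_dir, "vi_matrix.csv"))
    jsonlite::write_json(
      list(coarse = as.list(meta_coarse$labels),
           fine = as.list(meta_fine$labels)),
      file.path(out_dir, "meta_clusters.json"), auto_unbox = TRUE
    )
    for (pk in analysis_packets) {
      utils::write.csv(jaccard_maps[[pk]],
                       file.path(out_dir, paste0("jaccard_", pk, ".csv")),
                       row.names = FALSE)
    }
    manifest$outputs <- list(
      partitions = "partitions.csv", vi = "vi_matrix.csv",
      meta = "meta_clusters.json",
      jaccard = paste0("jaccard_", analysis_packets, ".csv")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  invisible(list(manifest = manifest, sim = sim, partitions = partitions,
                 vi = vi, meta_coarse = meta_coarse, meta_fine = meta_fine,
                 jaccard_maps = jaccard_maps))
}
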