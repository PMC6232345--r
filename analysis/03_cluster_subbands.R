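#!/usr/bin/env Rscript
# Stage 3: per-subband group connectivity and clustering.
#
# For a set of analysis packets spanning the planted bands and several
# noise-only bands, concatenates packet coefficients across subjects,
# computes Pearson correlation distances, clusters with average linkage and
# prunes to 5 clusters (the planted parcel count). Partitions and their VI
# against both ground-truth layers go to results/.

suppressPackageStartupMessages(library(wpfc))

dat <- read_dataset_nifti("results/data")
fs <- 1 / dat$ground_truth$tr_seconds
truth_a <- dat$ground_truth$layers$partition[[1]]
truth_b <- dat$ground_truth$layers$partition[[2]]

analysis_packets <- c("D6P0",                        # DC-adjacent, noise only
                      "D6P1", "D6P2", "D6P3",        # in / near layer A band
                      "D6P4",                        # 48-61 mHz: no planted
                                                     # signal, but adjacent to
                                                     # layer A (edge leakage)
                      "D6P10", "D6P11", "D6P12",     # inside layer B band
                      "D6P30", "D6P50")              # high-frequency noise

trees <- lapply(dat$datasets, function(ds) {
  wpt_decompose(ds$data, fs = fs, max_depth = 6)
})

partitions <- lapply(analysis_packets, function(pk) {
  grp <- concatenate_group(lapply(trees, packet_coefficients, address = pk))
  prune_to_k(average_linkage(correlation_distance(grp)), 5)
})
names(partitions) <- analysis_packets

dir.create("results", showWarnings = FALSE)
write.csv(
  data.frame(voxel = seq_along(truth_a), lapply(partitions, as.integer),
             check.names = FALSE),
  "results/subband_partitions.csv", row.names = FALSE
)

vi_truth <- data.frame(
  packet = analysis_packets,
  vi_vs_layer_a = vapply(partitions, variation_of_information,
                         numeric(1), partition_b = truth_a),
  vi_vs_layer_b = vapply(partitions, variation_of_information,
                         numeric(1), partition_b = truth_b)
)
write.csv(vi_truth, "results/vi_vs_ground_truth.csv", row.names = FALSE)

message("VI (bits) of each subband parcellation vs the planted layers:")
for (i in seq_len(nrow(vi_truth))) {
  message(sprintf("  %-6s  vs A: %5.2f   vs B: %5.2f", vi_truth$packet[i],
                  vi_truth$vi_vs_layer_a[i], vi_truth$vi_vs_layer_b[i]))
}
message("Packets inside a planted band should sit near 0 bits for their ",
        "own layer and far from the other.")
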