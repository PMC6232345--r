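#!/usr/bin/env Rscript
# Stage 1: synthesize the study dataset.
#
# Three subjects, 1000 gray-matter-like voxels, 900 volumes at TR = 0.645 s,
# 1/f^0.8 background, and two planted parcellations living in disjoint
# passbands: layer A (5 clusters) in 24-48 mHz, layer B (5 clusters) in
# 121-194 mHz, both at twice the noise SD. Volumes and ground truth are
# written under results/data/ as NIfTI + JSON.

suppressPackageStartupMessages(library(wpfc))

seed <- 20260921L
fs <- 1 / 0.645
out <- "results/data"

band_a <- packet_passband("D5P1", fs)
band_b <- c(packet_passband("D6P10", fs)[1], packet_passband("D6P15", fs)[2])
set.seed(derive_seed(seed, 10))
part_a <- sample.int(5, 1000, replace = TRUE)
set.seed(derive_seed(seed, 11))
part_b <- sample.int(5, 1000, replace = TRUE)

config <- simulation_config(
  n_voxels = 1000, n_subjects = 3, n_timepoints = 900, tr_seconds = 0.645,
  gamma = 0.8,
  planted_layers = list(
    list(passband = band_a, partition = part_a, amplitude = 2),
    list(passband = band_b, partition = part_b, amplitude = 2)
  ),
  mask_fraction = 1000 / 1728, seed = seed
)

sim <- synthesize_dataset(config)
mask <- generate_mask(c(12, 12, 12), 1000 / 1728, seed = derive_seed(seed, 1))
write_dataset_nifti(sim, mask, out)

message("Wrote ", config$n_subjects, " subjects to ", out,
        "; layer A band ", paste(signif(band_a * 1000, 3), collapse = "-"),
        " mHz, layer B band ", paste(signif(band_b * 1000, 3), collapse = "-"),
        " mHz")
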