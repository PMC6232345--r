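# wpfc — multispectral functional connectivity with wavelet packets

Resting-state BOLD fMRI fluctuations follow a `1/f^γ` power law (γ ≈
0.5–1), and functional-connectivity (FC) networks computed from different
frequency bands of the same scan need not agree. `wpfc` is an R package
for asking *where in the spectrum* FC structure lives:

* **Wavelet packet transform** — each voxel series is decomposed with a
  depth-6 Daubechies-7 (14-tap) filter bank into all 127 subband nodes
  `DdPp`, frequency-ordered so node `DdPp` occupies the nominal band
  `[p·(fs/2)/2^d, (p+1)·(fs/2)/2^d]` Hz with `fs = 1/TR`. The transform is
  periodized and exactly invertible from any full depth or disjoint packet
  subset.
* **Group connectivity per subband** — packet coefficients are pooled
  across subjects voxel-by-voxel, FC distance is the Pearson correlation
  distance `S1 = 1 − r`, and per-voxel graphs keep the nearest 5% of
  correlating voxels.
* **Clustering with inconsistency pruning** — average linkage
  (`S2(a,b) = mean cross-pair S1`, UPGMA) with dendrogram pruning either to
  a cluster count or at links whose inconsistency
  `Y4(k) = (z(k) − Y1(k))/Y2(k)` exceeds a threshold, with a local
  (`g = 2`) or global subtree window.
* **Partition comparison** — entropy `H(C) = −Σ P(i) log2 P(i)`, mutual
  information, and the variation of information
  `VI(C′,C″) = [H(C′) − I] + [H(C″) − I]` (bits), plus meta-clustering of
  the subbands themselves by their VI matrix.
* **Voxelwise Jaccard maps** — each subband's neighbour graph is compared,
  voxel by voxel, against a wideband reference rebuilt by inverse WPT of
  six packets spanning ~12–194 mHz, averaged across subjects.
* **Synthetic data with ground truth** — a generator plants
  band-limited, cluster-shared signals on `1/f^γ` backgrounds across
  subjects, so every stage is testable end to end without imaging data.

Intended users: researchers in frequency-resolved functional connectivity
and anyone needing a tested, deterministic reference implementation of
WPT-based multispectral network analysis at desk scale.

## Worked example

Plant a 4-cluster parcellation in the 24–48 mHz band over two subjects,
then recover it from the matching packet and fail to recover it from an
out-of-band packet:

```r
library(wpfc)

set.seed(derive_seed(1, 10))
truth <- sample.int(4, 300, replace = TRUE)
config <- simulation_config(
  n_voxels = 300, n_subjects = 2, n_timepoints = 900, gamma = 0.8,
  planted_layers = list(list(passband = packet_passband("D5P1", 1 / 0.645),
                             partition = truth, amplitude = 2)),
  seed = 1
)
sim <- synthesize_dataset(config)

trees <- lapply(sim$datasets, function(ds) wpt_decompose(ds$data, fs = 1 / 0.645))
recover <- function(pk) {
  grp <- concatenate_group(lapply(trees, packet_coefficients, address = pk))
  prune_to_k(average_linkage(correlation_distance(grp)), 4)
}
in_band  <- recover("D5P1")   # 24-48 mHz: carries the planted signal
out_band <- recover("D5P9")   # 218-242 mHz: 1/f noise only

variation_of_information(in_band, truth)   # 0.000 bits
variation_of_information(out_band, truth)  # 3.721 bits

ref <- build_wideband_reference(sim$datasets)
jd_in  <- voxelwise_jaccard_map(packet_neighbor_graphs(sim$datasets, "D5P1"), ref)
jd_out <- voxelwise_jaccard_map(packet_neighbor_graphs(sim$datasets, "D5P9"), ref)
mean(jd_in$mean_jd)   # 0.716
mean(jd_out$mean_jd)  # 0.972
```

The in-band packet reproduces the planted parcellation exactly (VI = 0
bits, against 3.72 bits for the noise-only packet — two unrelated
4-cluster labelings of 300 voxels sit near `2 log2 4`), and its neighbour
graphs are markedly closer to the wideband reference (mean Jaccard
distance 0.72 vs 0.97).

## Analysis workflow

The `analysis/` directory holds the narrative pipeline, each stage a thin
driver over package functions writing tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | 3 subjects × 1000 voxels × 900 volumes (TR 0.645 s), two planted 5-cluster layers (24–48 mHz and 121–194 mHz, amplitude 2) on `1/f^0.8` noise; writes NIfTI + ground-truth JSON |
| `02_decompose.R` | depth-6 WPT; per-packet energy table |
| `03_cluster_subbands.R` | group correlation distance, average linkage, 5-cluster parcellation per packet; VI against both planted layers |
| `04_compare_spectra.R` | all-pairs VI matrix; coarse (`g = 2`) and fine (global `g`) meta-clustering of the subbands |
| `05_voxelwise_jaccard.R` | top-5% neighbour graphs vs the six-packet wideband reference; Jaccard maps |

Run them in order with `Rscript analysis/01_simulate.R` etc. On the
default seed, stage 3 prints VI ≈ 0 bits for every packet inside a planted
band against its own layer (≈ 4.6 bits against the other), stage 4's
coarse meta-clustering groups `{D6P0–D6P4}` / `{D6P10–D6P12}` / noise
bands while the fine mode further splits the DC-adjacent `D6P0` from the
low-frequency group, and stage 5 reports mean Jaccard distances of ~0.84
(in-band) vs ~0.96 (out-of-band).

`run_pipeline()` performs the same simulate → decompose → cluster →
compare → map sequence as a single call with a run manifest.

## Documentation

The methods vignette (`vignettes/multispectral-connectivity.Rmd`) explains
the transform conventions (periodization, Gray-code frequency ordering),
the inconsistency-window and pruning semantics, what the synthetic
generator does and does not emulate, and the package's numerical choices
and limitations.
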