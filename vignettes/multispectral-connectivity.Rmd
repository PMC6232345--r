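---
title: "Multispectral functional connectivity with wavelet packets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral functional connectivity with wavelet packets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpfc)
```

## The problem

Resting-state BOLD fMRI signals scale like `S(f) ~ 1/f^gamma` with `gamma`
around 0.5–1, and growing evidence suggests that functional-connectivity
(FC) structure is not uniform across that spectrum: correlation networks
computed from different frequency bands of the same data can parcellate the
brain differently. `wpfc` implements a frequency-resolved FC pipeline that
makes this question operational:

1. decompose each voxel time series into dyadic subbands with a wavelet
   packet transform (WPT);
2. per subband, pool coefficients across subjects and compute Pearson
   correlation distances between voxels;
3. cluster each subband's distance matrix with average linkage and prune
   the dendrogram at its inconsistency cleavage points;
4. compare subband parcellations with the variation of information (VI)
   and meta-cluster the subbands themselves;
5. compare per-voxel neighbour graphs between each subband and a wideband
   reference with the Jaccard distance.

Because real multiband fMRI cannot ship with a package, `wpfc` includes a
synthetic-data generator whose defaults emulate the acquisition the
pipeline targets (TR = 0.645 s, 900 volumes, a handful of subjects), with
planted frequency-specific network structure providing ground truth for
every downstream stage.

## The wavelet packet transform

The WPT applies a paired low-pass/high-pass quadrature-mirror filter bank
recursively to *every* node (not only the low-pass branch, as the discrete
wavelet transform does), producing `2^d` equal-width subbands at depth `d`
and `2^(D+1) - 1 = 127` nodes for depths 0–6. A node is addressed `DdPp`,
and in frequency-ordered position its nominal passband is

```
[ p (fs/2) / 2^d , (p+1)(fs/2) / 2^d ]  Hz,   fs = 1/TR.
```

Three design choices matter here:

* **Filters.** `db7_filters()` constructs the Daubechies filter with 7
  vanishing moments (length 14) by spectral factorization of the Daubechies
  polynomial, rather than shipping a coefficient table; the unit tests
  verify orthonormality, the quadrature-mirror relation
  `g_n = (-1)^n h_{L-1-n}`, and all seven moment conditions to 1e-8. Seven
  moments buy sharp band edges at an acceptable 14-tap time support.
* **Periodization.** Filters wrap circularly. For even node lengths each
  split is an exactly orthogonal map (double-shift orthogonality makes the
  stacked analysis matrix orthonormal for *any* even length), so energy is
  conserved and reconstruction is exact. Odd-length nodes are first
  extended by one repeated sample (ceil-halving per level, never
  truncation); reconstruction truncates back, so perfect reconstruction
  still holds at every depth, while per-depth energy/count identities are
  exact only where no padding occurred (all depths for dyadic lengths;
  depths 0–2 for 900 samples). A 900-sample series leaves ~15 coefficients
  per depth-6 node.
* **Frequency ordering.** The natural filter-bank ordering is
  band-shuffled because downsampling mirrors the spectrum of every
  high-pass branch; the natural node `gray(p)` carries frequency band `p`.
  `frequency_order_positions()` exposes the Gray-code permutation, and all
  public addressing is frequency-ordered so the passband formula above
  holds. This was verified empirically with a sinusoid sweep (a tone's
  maximum-energy packet must bracket its frequency).

A practical caveat the tests quantify: with ~15–30 coefficients per node
against 14-tap circular filters, subspace projections leak a few percent of
energy outside their nominal band (the six-packet wideband reconstruction
keeps >90%, not >95%, of its energy inside 12–194 mHz on white input).
Nominal band edges should be read as approximate by one transition width.

## Group connectivity

For one packet, each subject contributes a voxel-by-coefficient block;
blocks are concatenated voxel-by-voxel across subjects into a group matrix.
Each subject's block is z-scored per voxel first (a documented toggle,
default on): pooled Pearson correlations otherwise overweight
high-amplitude subjects. FC distance is `S1 = 1 - r` over the concatenated
rows; zero-variance voxels have no defined correlation and are excluded
with a warning rather than silently imputed. Neighbour graphs mark each
voxel's `k = round(0.05 (n-1))` smallest-distance peers, self excluded,
with ties at the boundary broken toward the lower voxel index so graphs are
deterministic.

## Clustering and inconsistency pruning

Average linkage (UPGMA) merges the closest clusters under
`S2(a,b) = mean of all cross-pair S1`. The implementation wraps
`stats::hclust(method = "average")`; an independent brute-force O(n^3)
UPGMA oracle in the test suite checks merge heights and every induced flat
partition on hundreds of random instances.

Flat parcellations come from the dendrogram in two ways. `prune_to_k()`
removes the `k - 1` highest links. `prune_by_inconsistency()` uses the link
inconsistency `Y4(k) = (z(k) - Y1(k)) / Y2(k)`, where the window behind
`Y1` (mean) and `Y2` (sample SD, n−1 denominator) is the link plus the
links up to `g - 1` *levels* beneath it in the merge structure; `g = 2`
compares a link with its direct sub-links, and `g = "global"` pools its
entire subtree. Degenerate windows (single element, or zero spread) give
`Y4 = 0`. Two conventions deserve a note:

* *Why levels, not a fixed count of links.* If the window held exactly one
  link beneath, `Y4` would equal `1/sqrt(2)` for every link with a taller
  sub-link — an algebraic identity that makes "the most inconsistent link"
  an n-way tie. Windowing over the direct sub-links (the widely used
  dendrogram-inconsistency convention) restores a discriminative statistic
  while reproducing the same values wherever only one sub-link exists.
* *Cutting semantics.* Cutting a link also removes everything above it: a
  cluster forms at a node only if the node and all of its sub-nodes are
  consistent. Thresholds below the minimum give all singletons; at or
  above the maximum, one cluster; raising the threshold never increases
  the cluster count.

`leaf_order()` returns the dendrogram-consistent traversal order (children
of every merge contiguous, left child first). For cophenetic
dissimilarities every consistent order attains the same adjacent-pair sum,
so the deterministic traversal is used rather than an optimization that
cannot change the objective; it is still never worse than the arbitrary
insertion order, which the tests check.

## Comparing parcellations

Entropy, mutual information and VI use log base 2 throughout (units: bits)
with `0 log 0 := 0`. VI is a true metric on partitions — symmetric, zero
iff equal up to relabelling, triangle inequality — which the suite verifies
on a thousand random triples. Raw (unnormalized) VI is reported; a
`normalized = TRUE` variant (divide by `log2 n`) exists but is off by
default.

`cluster_spectra()` turns the packet-by-packet VI matrix into a
meta-clustering of subbands, reusing the same linkage/inconsistency
machinery. Coarse mode cuts exactly the link(s) attaining the highest
local (`g = 2`) inconsistency — the single sharpest change in linkage
distance across the spectrum. Fine mode operationalizes "remove the first
global inconsistency among the designated band" as: among links whose both
children contain at least one designated packet (by default those with
passbands below 0.1 Hz), find the lowest one with positive global
inconsistency and cut every link at least that inconsistent. When the
designated packets agree perfectly there is nothing to remove and fine
mode returns a single group — the analysis scripts therefore include
heterogeneous low-frequency packets when exercising it.

## Voxelwise Jaccard comparison

The wideband reference is built per subject: inverse WPT keeping only six
packets spanning ~12–194 mHz (`D6P1, D5P1, D4P1, D5P4, D5P5, D4P3`; fully
configurable), then correlation distance and the top-5% neighbour graph.
Each subband's per-subject graph is compared voxel by voxel with the
Jaccard distance (binary, unweighted sets — correlation magnitudes are
discarded after thresholding), and maps report the mean and SD across
subjects. Subject-level graphs, not group-concatenated ones, feed this
stage, since the maps are averages over subjects. Note a subtlety the
tests document: a graph built from one packet's *coefficients* and a graph
built from that packet's *reconstructed series* agree only up to centering
effects (coefficient means are not series means), so the single-packet
consistency check asserts near-agreement, not identity.

## The synthetic generator

What it emulates: per-voxel `1/f^gamma` backgrounds (`gamma` defaults to
0.8, the middle of the 0.5–1 range reported for BOLD) synthesized by
spectral shaping — multiply the FFT of white noise by `f^(-gamma/2)`, zero
the DC bin, invert — so the expected periodogram follows the target law
exactly and the fitted spectral exponent is recoverable to ±0.1; planted
"layers", each a parcellation whose clusters share a band-limited signal
built by hard FFT-bin masking (band-energy assertions are then exact);
voxelwise z-scoring after summing layers and noise; multiple subjects that
share partitions but not realizations; and a blobby mask from a
thresholded smoothed Gaussian random field, with voxel order fixed as
`which(mask)` (column-major).

What it does not emulate: motion, physiological noise, spatial smoothing,
hemodynamic convolution, spatial autocorrelation of the noise, or any
anatomy. Passing the planted-recovery suite therefore shows the pipeline
correctly extracts frequency-specific network structure *when it exists at
the configured contrast*; it says nothing about effect sizes in real
brains.

The end-to-end validation (`planted_recovery_experiment()`) fixes the
study conditions: 1000 voxels, 900 timepoints, 3 subjects, two 5-cluster
layers at amplitude 2 (signal SD twice noise SD) in 24–48 mHz and 121–194
mHz. Three checks must hold: the parcellation recovered inside each
planted band is closer in VI to its own layer than to the other; coarse
meta-clustering groups same-band packets and separates the bands; and
in-band packets sit closer (lower mean Jaccard distance) to the wideband
reference than an out-of-band control. Each check is required in at least
9 of 10 seeded replicates. Five clusters per layer keeps VI contrasts
interpretable (identical recovery gives VI = 0; unrelated 5-cluster
partitions of 1000 voxels sit near 4.6 bits).

## Numerical choices and degenerate inputs

* All randomness flows from one user seed through `derive_seed()`
  (multiplicative hashing mod 2^31 − 1), so every run is bit-reproducible
  and per-subject/per-stage streams are decoupled.
* Correlation distances are symmetrized (`(d + t(d))/2`) and the diagonal
  forced to zero to absorb floating-point asymmetry.
* VI is clamped at zero against rounding; merge ties in `hclust` are
  resolved by its deterministic internal order (test oracles use
  continuous random distances, where ties have probability zero).
* `jaccard_distance()` on two empty sets is undefined and raises a classed
  error (`wpfc_jaccard_undefined`) rather than returning a sentinel; it
  cannot occur in pipeline use because neighbour sets have `k >= 1`.
* A memory guard on `n_voxels * n_timepoints` (default 5e7) and the dense
  distance-matrix design bound problem sizes; whole-brain scale would need
  chunked distances, which is out of scope.

## Problem sizes

The shipped analyses and tests run at deliberately modest scale — 1000
voxels, 3 subjects, 900 timepoints for the study-scale experiment (about
10 s per replicate), and 40–200 voxels for module tests — chosen so the
whole validation suite completes in a couple of minutes while still
exercising every code path at the study's native TR and scan length.

## Known limitations

* Periodized filtering wraps series ends; for strongly non-stationary
  boundaries a reflection mode (not implemented) would leak less.
* Nominal passbands ignore filter transition bands; adjacent packets see a
  few percent of each other's energy, and a layer planted flush against a
  band edge is partially recovered by the neighbouring packet (the
  analysis scripts show this deliberately).
* The fine-global spectral pruning depends on a designated-band input; it
  is a faithful operationalization of a verbal rule, not a canonical
  algorithm.
* Dense matrices cap practical problem size at ~20k voxels.
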