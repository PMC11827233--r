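---
title: "Detecting prevalent chromosome morphologies in single-cell 3D genome structures"
author: "chromomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting prevalent chromosome morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chromatin loops, TADs and compartments are averages: at the single-cell
level the 3D fold of an entire chromosome varies enormously from nucleus to
nucleus. Given a large ensemble of single-cell 3D genome structures --
modeled diploid genomes at 200-kb bead resolution, chromatin-tracing
coordinates, or (indirectly) sparse single-cell Hi-C maps -- the question
`chromomorph` answers is: *do chromosomes occupy a small number of
recurrent territory morphologies, and what distinguishes them?*

The package detects such morphology clusters, profiles each cluster's
structure and position within the nuclear topography, and classifies
external single-cell observations against the detected states.

## The model and procedure

### Input representation

Each chromosome copy of each cell is an ordered chain of beads of radius
$R_{bead} = 118$ nm (200-kb chromatin per bead; genome-to-nucleus volume
ratio 0.4 in a 5-µm-radius spherical nucleus). Unrestrained (`cen`) beads
are removed. A structure is summarized by its surface-to-surface distance
matrix
$$d_{ij} = \lVert x_i - x_j \rVert_2 - 2 R_{bead},\qquad d_{ii} = 0,$$
negative gaps (overlapping beads) clipped to zero, scaled so the maximum
entry is 1, and resized by bilinear interpolation to a side divisible by
50 (the pooling factor of the autoencoder below). The matrix is treated as
a grayscale image of the fold.

### Two-step dimension reduction

1. **Convolutional autoencoder.** Encoder: three convolution layers of
   16, 8 and 4 filters (10 × 10 kernels, stride 1, same padding, ReLU),
   each followed by max pooling (5 × 5, 5 × 5, 2 × 2). Decoder: mirror
   image (4, 8, 16 filters with nearest-neighbour upsampling 2, 5, 5) and
   a final single-filter sigmoid layer, so outputs stay in $[0,1]$.
   Training minimizes the mean squared reconstruction error with Adadelta
   (no learning-rate tuning; $\rho = 0.95$), 15 epochs, batch 200, after
   shuffling the set. The latent matrix is $(side/50)^2 \times 4$ values
   -- a fixed 625-fold compression regardless of chromosome length. The
   latent cube is flattened column-major (rows, columns, then channels)
   and each latent dimension is z-scored across the set (zero-variance
   dimensions are set to 0).
2. **t-SNE.** The standardized latent vectors are embedded into 2D by
   exact t-SNE (Kullback–Leibler divergence between Gaussian input
   affinities and Student-t output affinities), learning rate 1000,
   1000 iterations with early exaggeration 12 for the first 250 and
   momentum 0.5 → 0.8. Perplexity is 200 at full scale (20,000
   structures); see *Desk-scale parameters* below.

A generic `alternative_embed()` hook provides PCA, classical MDS, Isomap
and spectral embedding for comparison.

### Density clustering

Embedding outliers are removed by the 3-sigma rule on the row sums of the
pairwise distance matrix. A bivariate Gaussian kernel density with
Scott's-rule bandwidth ($h_j = \hat\sigma_j n^{-1/6}$ per axis) is
evaluated on a square grid spanning the points. Peaks are cells equal to
their 5 × 5 maximum-filter value and nonzero (exact plateau ties collapse
to the lexicographically smallest index). Each peak's basin is found
watershed-style: the density level rises through 100 evenly spaced levels
from 0 to the maximum until the enclosing super-level component (8-connected)
contains only that peak; points whose grid cell falls inside the component
get the peak's label. Clusters below the minimum size (100 at full scale)
are discarded. Quality is reported as the mean and per-cluster silhouette
of the clustered points, and cluster occupancy as each cluster's share of
all clustered structures.

### Cluster profiling

Per cluster and for the ensemble of clustered structures:

* **Contact matrix** `cm_ij = 1` iff $\lVert x_i - x_j\rVert \le 3R_{bead}$
  (inclusive), summed over members; **average distance matrix** = mean of
  min–max-normalized center-distance matrices.
* **Insulation score** along the diagonal with window $l$: contact variant
  $\langle E, LM\rangle + \langle E, RM\rangle - \langle E, M\rangle$;
  distance variant binarizes the average distance matrix at 0.45 (the
  reference range is 0.4–0.5) and scores
  $\langle E, M\rangle - \langle E, LM\rangle - \langle E, RM\rangle$.
  **Territory-domain boundaries** are called in two passes: coarse window
  40 Mb (200 bins) locates candidate regions as local maxima with
  prominence ≥ 1 profile sd, a fine 6-Mb (30-bin) window pinpoints the
  boundary bin. Boundary significance is the z-score of the fine profile
  at the boundary with the denominator floored at the counting-noise sd
  $\sqrt{2 p (1-p)}\, l$ of the binarized window sums -- without the floor
  a near-flat null profile turns trivial fluctuations into huge z values.
* **P(s)**: mean contact frequency per sequence-separation band.
* **Radius of gyration** of the 1-Mb (5-bin) window centered on each bin,
  and per-structure whole-chromosome RG.
* **Radial position** $r = \lVert x\rVert / R_{nuc}$ (sphere) or the scaled
  elliptic radius (ellipsoid); **δRAD** = $\log_2(\sigma_i/\bar\sigma)$ of
  the radial positions (zero-variance bins are `NA` rather than $-\infty$).
* **A/B compartments**: observed/expected by separation-band means,
  Pearson correlation matrix, leading eigenvectors. Both PC1 and PC2 are
  returned (the compartment signal can surface in either) and signs are
  oriented by correlation with a user-supplied reference track.
* All cluster-vs-ensemble comparisons use `log2(cluster/ensemble)` tracks
  (RadRatio, RgRatio, SpdRatio, SafRatio, IppRatio, TSA ratio).

### Nuclear topography

Speckle locations are predicted per cell: a graph over A1-subcompartment
beads with edges below $4R_{bead}$ center distance is partitioned by a
native Markov Cluster implementation (expansion 2, inflation 2, pruning
1e-5); every subgraph of more than 3 nodes yields a speckle at its
geometric center. From the speckles: SpD (surface distance to the nearest
speckle, cluster mean), SON TSA-seq
($\sum_l e^{-k d_{il}}$ with $k = 4$ per µm -- distances in micrometers;
the reference leaves the unit implicit but $k=4$ is the TSA-decay constant
per µm), SAF (fraction of structures with nearest-speckle distance below
1000 nm for models, 500 nm for tracing data), and inter-chromosomal
proximity (IPP; contacts within $R_{soft} = 2$ µm, intra-chromosomal part
from the same homolog copy only, inter parts averaged over both copies).

### Classifying external single-cell data

*Sparse single-cell Hi-C*: each raw cell matrix is convolved with an
11 × 11 box filter, row-normalized into a transition matrix, imputed by a
random walk with restart ($R_t = (1-p) R_{t-1} M + pI$, $p = 0.5$, to
Frobenius residual ≤ 1e-6) and binarized per row at the 75th percentile.
Cluster masks derive from
$d_{ij} = \log_2( S_A m^{Pop}_{ij} / (S_{Pop} m^{A}_{ij}))$: superiority
where $d \ge 5$, inferiority where $d \le -1$ (entries with a zero count on
either side are undefined and excluded; the asymmetric thresholds are as
printed in the reference method). The score
$s^{(A)} = \exp(\langle M, M_{inf}\rangle/\langle E, M_{inf}\rangle -
\langle M, M_{sup}\rangle/\langle E, M_{sup}\rangle)$ assigns a cell to the
top cluster when the top-two margin is at least 0.01; shuffled-matrix
controls (off-diagonal entries permuted, diagonal and totals preserved)
calibrate the false-assignment rate.

*Chromatin tracing*: cluster average distance matrices are downsampled to
the imaged loci; both the structure's and the cluster's flattened upper
triangles are min–max normalized and compared by Pearson correlation,
score $e^r$, assignment margin 0.05. The score is invariant to global
scaling of the coordinates.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class the pipeline consumes, each
deterministic given its seed.

* **References**: per cluster, a confined random-walk backbone whose
  planted territory domains are collapsed around displaced centers,
  giving block-structured distance matrices with boundaries at known bins.
* **Positive controls**: replicates scatter around a reference at noise
  levels $\sigma \in \{0.1, 0.4, 0.8\}$. The default noise space adds
  Gaussian noise of $\sigma$ *micrometers* to the surface-distance matrix
  entries before per-matrix max-normalization. This choice was selected
  among three implemented readings (coordinate noise relative to the
  reference RG; unit-normalized matrix noise; micrometer matrix noise)
  because it is the only one under which replicates scatter *around* their
  reference at every level -- distance matrices are micrometer-scale
  length data, and entry noise leaves the expected pattern at the
  reference, whereas large coordinate noise systematically inflates all
  distances and turns each noise level into its own morphology. For the
  same reason each noise level forms its own dataset and is clustered in
  its own run (per-matrix normalization makes the noise level itself a
  systematic feature, so mixing levels in one run splits every reference
  into per-level subclusters -- with perfect reference purity, but more
  than 4 clusters).
* **Negative controls**: self-avoiding homopolymers (bond $2R_{bead}$,
  excluded volume $2R_{bead}$) confined to the nucleus.
* **Speckle fixtures**: genomes whose A1 beads sit in a known number of
  tight blobs with recorded centers.
* **Single-cell maps**: Bernoulli-sampled from cluster contact
  probabilities, thinned to ~3879 expected contacts per cell (the
  observed sparse single-cell coverage at 200-kb resolution).

What passing these tests shows: the pipeline separates genuinely distinct
territory-domain morphologies under realistic noise, does not hallucinate
domain boundaries on unstructured polymers, and degrades gracefully with
sample size. What it does not show: performance on real populations with
continuous (non-planted) morphology variation, imaging noise models, or
experiment-specific missingness.

## Desk-scale parameters

The reference analysis runs at 20,000 structures per chromosome with a
1000 × 1000 density grid, minimum cluster size 100 and t-SNE perplexity
200. The package's defaults scale these to desk-sized problems and are
restored to the full-scale constants by `paper_scale = TRUE`:

| parameter | desk default | full scale | rationale |
|---|---|---|---|
| autoencoder input side | 100 | nearest multiple of 50 | smallest side where the 5·5·2 pooling stack keeps a spatially resolved 2 × 2 × 4 latent; at side 50 the latent collapses to 1 × 1 and the ReLU decoder can die at initialization |
| KDE grid | 500 | 1000 | resolution tracks point count |
| min cluster size | 30 | 100 | scales with input size |
| t-SNE perplexity | 50 | 200 | perplexity is an effective neighbourhood size (~1% of the full runs); it must stay below the per-cluster count or clusters merge structurally |

The packaged studies use: positive controls of 4 references × 200
structures per noise level (three runs), a 1000-polymer negative control,
a 6-cluster unequal-occupancy population (540 structures) subsampled
100/50/25% for the robustness check, and 200 synthetic cells (plus 200
shuffled controls) for the single-cell Hi-C recovery.

## Numerical choices and degenerate inputs

* Bilinear resizing fixes the endpoints (corner values preserved; exact on
  constant and index-affine matrices); "nearest multiple of 50" rounds
  ties down.
* Negative surface distances are clipped to zero before max-normalization.
* KDE with a degenerate (zero-spread) axis jitters by 1e-9 of the span.
* Max-filter plateau ties collapse to the lexicographically smallest cell.
* A peak that never isolates within the 100 watershed levels keeps no
  basin (its points stay unclustered).
* Zero-variance latent dimensions standardize to 0; `log2` ratio tracks
  are `NA` where the ensemble value is non-positive; δRAD is `NA` where
  the radial sd is 0.
* All-zero rows in single-cell matrices stay zero through imputation (with
  a warning); empty score masks contribute 0.
* The intra-cluster Wasserstein split follows the half-versus-reversed-
  complement indexing of the reference; Euclidean/Gaussian intra values
  use sampled distinct pairs (the reference is silent), so a cluster
  compared with itself reports a log2 ratio of exactly 0.

## Known limitations

* The autoencoder and t-SNE are single-threaded CPU implementations: full
  20,000 × (850-bin) runs are hours of CPU, as in the reference analysis.
* Exact t-SNE is quadratic in the number of structures; beyond ~20,000
  points a Barnes–Hut approximation would be needed.
* LLE and UMAP are recognised but unimplemented embedding hooks.
* X-chromosome copies are out of scope (clustering is defined for
  autosomes); bins are fixed-width.
* Speckle prediction assumes A1 annotations; lamina-distance features are
  only available as radial-position derivatives.
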