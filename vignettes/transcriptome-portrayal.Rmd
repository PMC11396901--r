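---
title: "Transcriptome portrayal with metagene self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome portrayal with metagene self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portraitSOM)
```

## The model

portraitSOM analyzes a gene-level, log-scale expression matrix (genes x
samples) by *portrayal*: a self-organizing map (SOM) with `rows x cols`
neurons is trained on the gene profiles, so that each neuron holds a
*metagene* — the neighborhood-weighted mean profile of the genes it
collects — and each gene is assigned to its best matching unit (BMU), the
Euclidean-nearest metagene. Because the lattice is topology-preserving,
nearby neurons collect genes with similar expression profiles, and the
metagene values of a single sample can be drawn as a two-dimensional
image, its *portrait*. Regions of coordinated over-expression appear as
red "spots"; these are segmented into *spot modules* (connected lattice
regions plus their gene lists), which act as data-driven co-regulation
clusters. Sample-level structure is read from the pairwise correlation of
portraits, from independent component (IC) coordinates of the sample
cloud, and from a small second-level SOM trained on the samples
themselves. Spot gene lists are interpreted by hypergeometric
overrepresentation against user-supplied gene sets (GMT).

The motivating application is a two-cultivar grapevine water-stress time
course: two cultivars with contrasting water-management strategies
(isohydric vs anisohydric), well-watered (CTRL) and water-stressed (STRS)
arms, three timepoints (2, 6, 27 days) and three biological replicates —
36 samples. The package ships a simulator for exactly this design so the
whole pipeline is testable without any external download.

## Preprocessing scale

The SOM is trained on *gene-centered* data: each gene's mean over **all**
samples is subtracted (`center_genes()`), so metagene values express
above/below-mean regulation and group "waterline" portraits compare each
condition against the grand mean. Centering is deliberately global, not
per group. Missing values are a hard error rather than imputed — the
intended input is complete, RMA-style normalized intensity data, and
silent imputation would distort spot segmentation. Optional quantile
normalization (`quantile_normalize()`, off by default) forces identical
column distributions with averaged rank ties; it precedes centering.

## SOM training

`train_som()` implements a *batch* SOM: per epoch, all genes are assigned
to their BMU and every metagene is recomputed as the Gaussian-
neighborhood-weighted mean of the assigned profiles. Batch training is
deterministic given the initialization, which makes runs reproducible
bit-for-bit — a property the test suite asserts end to end.

Tunable parameters (defaults in parentheses):

* `rows`, `cols` (40 x 40): lattice size; 1600 metagenes match the
  published configuration for ~30,000-gene arrays. Tests use 20 x 20 and
  smaller, which preserves all qualitative behavior at a fraction of the
  cost.
* `n_epochs` (50) and the neighborhood radius, decaying linearly from
  `radius_start` (half the larger lattice side) to `radius_end` (0.5
  lattice units). The large initial radius orders the map globally; the
  sub-unit final radius sharpens cluster borders.
* `init` (`"pca_plane"`): metagenes are seeded on the plane of the first
  two principal axes of the gene cloud, scaled by the projection spreads,
  with a fixed sign convention — this pins the map orientation, so even
  the initialization is reproducible without a seed. `"random"` is
  available for robustness checks.

Numerical choices: BMU ties go to the lowest row-major neuron index
(coordinates are 1-based with row 1, col 1 top-left — the R convention);
empty neurons keep their neighborhood-smoothed metagene and simply carry
an empty gene list; the per-epoch quantization error (mean gene-to-
metagene distance) is recorded after every update and is non-increasing
in practice, which the tests check at a 1e-9 slack.

## Spot segmentation

The *overexpression map* collapses the metagenes to their per-neuron
maximum over samples; spots are the 8-connected components of neurons
strictly above the 0.75 quantile of that map (`segment_spots()`), with
components under `min_size = 4` neurons discarded as speckle, and are
labeled A, B, C, ... by descending peak value (`label_spots()`). The
strict inequality makes constant maps yield no spots; 8-connectivity
matches the blob-like shape of real spots. A spot is *active* in a sample
(or group) when its mean gene profile there exceeds half its maximum over
subjects, the maximum being required positive — the activation criterion
is a package decision, as published portrayals show activation networks
without defining one.

## The synthetic data generator

`generate_expression()` plants six module archetypes on the factorial
design, mirroring the canonical spot patterns of the motivating study:
A up in all anisohydric (SG) samples and down in the isohydric (MP) ones;
B its mirror; C and D transient peaks at the first and second timepoint
in both cultivars; E high at the last timepoint in SG-STRS and MP-CTRL;
F the late shared stress response (high at the last timepoint under STRS
in both cultivars). Amplitudes are +/-1 on the centered log scale — a
unit effect size that makes thresholds interpretable — with 400 genes per
module (mid-range for co-regulation modules of a few hundred genes),
12,000 genes in total, i.i.d. Gaussian replicate noise of sd 0.2 on
module genes and a background pool of sd 0.1. Replicate correlation
arises only through shared group means. The generator emulates the
factorial design, planted co-regulation and a low-variance background; it
does **not** emulate probe-level effects, batch structure, or — most
importantly — the continuum of intermediate, small-amplitude expression
patterns that fills the space between co-regulation modules in real
data. Passing recovery tests therefore demonstrate that the machinery
finds planted structure; they do not certify behavior on the full
complexity of real arrays.

### A known limitation of module recovery

On this synthetic design the six planted modules are *collected*
essentially perfectly — in every tested configuration at least 90% (in
practice 100%) of each module's genes land inside a single spot — but
they are not always *separated*: segmentation typically returns two to
five spots, with some pairs of modules merged. The cause is structural.
After gene centering, most archetype pairs share samples in which both
are positive (A is positive in every SG sample, so it overlaps C, D, E
and F there; E and F share the SG stress endpoint). Wherever two module
territories are adjacent on the lattice, the interpolating border
neurons inherit those shared positive coordinates, so the overexpression
map stays high (~0.3-0.9) across the border — far above the segmentation
threshold, which sits at the top of the background "sea" (~0.2-0.4). And
adjacency is the energetically preferred arrangement, because the direct
distance between module centroids is shorter than the detour through the
background blob. Real data avoids this because intermediate-profile,
low-amplitude genes win the border neurons and pull the map down between
spots. This behavior was verified across lattice sizes (20-40 per side),
both initializations, five radius schedules and ten seeds; the
corresponding recovery expectation in the acceptance tests documents it
as a failing check rather than being weakened.

## Sample space

The portrait correlation map is Pearson correlation between metagene
columns. Cluster number is chosen by maximum mean silhouette over
average-linkage hierarchical clustering of the distance `1 - r`
(`cluster_count()`), an operationalization of "distinct clusters" that is
otherwise a visual call; degenerate all-alike inputs fall back to the
smallest candidate k. Independent components are computed on the sample
vectors in metagene space — not on the correlation matrix itself, which
is the information-preserving choice — by whitening to k principal
dimensions and fixed-point negentropy ICA (tanh contrast, symmetric
decorrelation). ICA is order- and sign-ambiguous, so components are
ordered by the explained variance of their back-projection and oriented
so the largest-magnitude score is positive, and each component is
reported together with the design factor it correlates with best
(point-biserial for binary factors, Spearman against day for time). This
makes trajectory statements testable without fixing arbitrary axes: on
the default synthetic data one component matches cultivar with |r| above
0.9 and a different one matches time. The second-level sample SOM uses
the same batch trainer on a small (10 x 10) grid.

## Enrichment

Overrepresentation is the one-sided hypergeometric upper tail
`P[X >= k]` for the overlap between a query list and each set, both
intersected with the universe (by default the model's full gene list —
the choice of universe is configurable since published analyses rarely
state it), followed by Benjamini-Hochberg adjustment across the sets of
one collection. There is deliberately no ranked (GSEA-style) statistic:
spot gene lists are hard selections, for which the hypergeometric test is
the appropriate tool. Pathway gene sets can additionally be mapped onto
the lattice (`map_gene_set_to_portrait()`) and colored by the
experimental group with the highest mean waterline value at each gene's
BMU (`condition_color_assignment()`), with documented first-in-order tie
breaking.

## Pipeline and reproducibility

`run_pipeline()` chains the stages from a single YAML-storable config and
writes every artifact plus a manifest with MD5 checksums. Each stochastic
stage derives its seed deterministically from the master seed and the
stage name, so adding stages never shifts existing random streams and two
runs with the same config are bit-identical. Problem sizes in the test
suite are scaled down (hundreds to thousands of genes, 8-20 neuron grid
sides, 12-30 epochs) — chosen as the smallest sizes at which every
qualitative property of the full configuration is still expressed.

## Limitations

* Spot separation on the bundled synthetic design merges correlated
  modules (see above); gene collection is complete, spot identity is not.
* The training schedule is a package decision; published portrayals do
  not state one, so only schedule-robust properties (module collection,
  factor recovery, determinism) are asserted, not bit-level
  reproduction of any published map.
* The simulator's noise model is i.i.d. Gaussian on the log scale; array
  batch effects and probe-level artifacts are out of scope.
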