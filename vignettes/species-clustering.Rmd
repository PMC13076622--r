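---
title: "Unsupervised tree species clustering from LiDAR crowns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised tree species clustering from LiDAR crowns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowncluster)
library(dplyr)
```

## The problem

Terrestrial and airborne LiDAR campaigns routinely deliver point clouds
already delineated into individual trees, but not their species. Supervised
classifiers need labelled training sets that rarely transfer between regions,
scanners, and forest types. `crowncluster` takes the opposite route: it groups
trees into species-like clusters with no training data at all, using only the
3D shape of each crown, and then lets the user attach species names by
labelling a handful of trees per detected group.

The pipeline is: per-tree shape descriptors → rank-fused pairwise similarity
graph → modularity-based community detection → majority-vote labelling, with
Rand / Adjusted Rand agreement against ground truth where available.

## The shape descriptor

Each tree is reduced to 23 numbers in six feature sets, all computed relative
to the crown's centre of mass so the descriptor is invariant to translation
and — by construction of the symmetrised grid — insensitive to rotation about
the vertical axis:

* **f1 (3)** — principal component spreads. PCA on the raw coordinates gives
  standard deviations $d_1 \ge d_2 \ge d_3$ along the principal directions;
  the feature is $[d_1-d_2,\; d_1-d_3,\; d_2-d_3]$. Exactly invariant to any
  rigid motion.
* **f2 (1)** — global rotational symmetry. A count grid $V$ with isotropic
  voxel edge $\delta$ (0.5 m default) is symmetrised into $S$ by revolving
  the points around the vertical axis through the centre of mass: a point at
  horizontal radius $r$ occupies every voxel of its z-slice whose centre
  radius is within $\delta$ of $r$. $f_2$ is the Jaccard index of the
  binarised grids; occupied $V$ voxels are always occupied in $S$, so
  $f_2 = |V^{(b)}|/|S^{(b)}| \in (0, 1]$, with 1 a perfectly symmetric crown.
* **f3, f4, f5 (6 each)** — vertical profiles: per-slice Jaccard symmetry,
  per-slice $S$ point counts, and per-slice maximum point radius, each
  compressed to 6 cubic B-spline coefficients.
* **f6 (1)** — the L1 residual of the f3 profile fit, a roughness measure.

### Numerical choices

* **Grid anchoring.** The grid origin is the bounding-box minimum snapped so
  the centre of mass lies at a voxel centre in x and y. This makes the radial
  symmetrisation condition symmetric and the degenerate axis-only tree exact
  ($f_2 = 1$).
* **Half-open binning and the slice tie.** Points bin into voxels by
  half-open intervals. The symmetrisation z-condition $|l_z - s_z| <
  \delta/2$ is strict; a point lying exactly on a slice boundary would
  otherwise fall out of its own slice and could break the $V^{(b)} \subseteq
  S^{(b)}$ containment on measure-zero inputs, so the point's own z-bin is
  always included. On generic data the two rules are identical.
* **Spline basis.** Exactly 6 cubic B-spline basis functions on a uniform
  open knot vector over [0, 1] (slice midpoints rescaled), fitted by
  unpenalised linear least squares — the reproducible choice when a penalty
  weight would otherwise be a hidden free parameter. Profiles shorter than
  the basis use the SVD minimum-norm solution, which is exact and
  deterministic. Slices empty in both grids are dropped before fitting: the
  Jaccard index is undefined on an empty union and such slices are artefacts
  of $\delta$.
* **Minimum viable tree.** At least 10 points spanning at least 2 occupied
  z-slices; smaller inputs are rejected with a named error rather than
  producing meaningless descriptors.
* **Descending order in f1** makes all components non-negative and the
  feature well defined under eigenvalue ties.

## From features to a graph

Feature sets live on incommensurable scales (metres, counts, dimensionless
ratios), so distances are never mixed directly. For each feature set,
pairwise distances (absolute difference for scalars, cosine distance for
vectors) are converted to standard competition ranks ("1224": ties share the
smallest applicable rank), and an edge weight is the rank product

$$w_{uv} = \prod_f \left(1 - \frac{R_f(u,v)}{\max R_f}\right)^{\alpha}.$$

Two properties matter. First, any strictly increasing transform of one
feature's distances leaves every rank — hence the whole graph — unchanged;
this is the core robustness of rank fusion and is tested byte-for-byte.
Second, the cosine distance ignores overall scale, so uniformly densifying or
thinning a cloud moves the per-slice count feature f4 along a ray and leaves
its distances unchanged — the mechanism behind point-density robustness.

The lowest-weight share $\beta$ of edges is then discarded. Pruning orders
edges by the $\alpha$-independent rank product $\prod_f (1 - R_f/\max R_f)$:
for every $\alpha > 0$ this ordering coincides with the weight ordering, and
at $\alpha = 0$ — where all weights flatten to 1 and only topology carries
information — it keeps the pruning informative instead of degenerating into a
tie-break. Edges whose rank product is exactly zero (some feature at its
maximum rank) are always dropped and count toward the pruned share first;
they carry no modularity signal. Ties at the pruning cut resolve by
lexicographic tree-id pair so runs are byte-identical.

Defaults are $\delta = 0.5$ m, $\alpha = 2$, $\beta = 0.1$. $\alpha$ sharpens
the contrast between strong and weak edges and so raises the number of
detected communities; $\beta$ strands weakly connected trees, which is also
the lever for outlier isolation ($\beta = 0.7$ in `outlier_community_size()`).

## Community detection

`detect_communities()` implements weighted fast greedy modularity
optimisation (Clauset–Newman–Moore agglomeration) natively: starting from
singletons, repeatedly merge the community pair with the largest modularity
gain $\Delta Q = 2(e_{ij} - a_i a_j)$ while any gain is positive. Ties break
on the smallest community-index pair, making the detector fully
deterministic — the reason it is implemented in-package rather than delegated
(an igraph cross-check runs in the test suite, and an optional stochastic
Leiden back-end is available behind `method = "leiden"`, outside the default
path). Isolated nodes remain singleton communities; an edgeless graph
reports $Q = 0$ with a warning. On graphs small enough to enumerate, the
greedy $Q$ is verified against the exhaustive optimum over all partitions.

Majority voting then labels each community from `k` uniformly sampled
labelled members (ties to the lexicographically smallest species; sampled
trees keep their own label), and `classification_scores()` reports the
confusion matrix with macro-averaged precision, recall, specificity and F1 so
imbalanced species cannot dominate. Mean-weight outlier ranks are computed on
the unpruned complete weight matrix, since a candidate's isolation should not
depend on the pruning level chosen for clustering.

## The synthetic forest

`simulate_forest()` exists so every stage is testable without downloads. A
species is a solid of revolution: six control radii interpolated over the
crown, a bare trunk below, azimuthal asymmetry
$r(z)(1 + a\cos(\theta - \varphi_0))$ with a random per-tree phase, Gaussian
jitter, and a Poisson point count at `density` points per m³ of crown volume
(crowns are filled volumetrically, not surface-only, because terrestrial
LiDAR returns arise throughout the crown and the per-slice count feature
needs interior mass). Heights draw uniformly per tree and radii scale
proportionally, so a species is a shape, not a size. One master seed derives
independent per-tree child seeds, so generation is reproducible and
order-free.

Two calibrated packs ship with the package:

* **default10** — ten archetypes (spire and high-crowned columnar conifers, a
  globe, a vase, an umbrella, a low dome, a bilobed crown, a high-crowned
  layered form, a strongly asymmetric weeping form, a broad flat-topped oak),
  ~5000 points per tree. The archetypes were designed jointly against the
  descriptor: because vector-feature distances are cosine (shape, not size),
  species must differ in profile *shape*, crown-base height, or asymmetry —
  not merely in crown radius — to be separable. The pack is deliberately well
  separated: at the defaults the full pipeline recovers all ten species
  exactly (ARI = 1), which is what the end-to-end acceptance checks assert.
* **hard7** — seven overlapping broadleaf/conifer profiles with higher noise
  and asymmetry and imbalanced class sizes (164/183/22/39/158/25/100),
  emulating the difficulty of a real terrestrial campaign where morphologies
  overlap and communities merge.

What the generator does **not** emulate: branching architecture, occlusion
and scanner geometry, understory clutter, co-registration noise, or
segmentation errors from tree delineation. Passing tests on `default10`
therefore demonstrate correctness of the pipeline and its invariances, not
field-grade accuracy on real scans — `hard7` probes the merging regime, but
real-data performance must be established on real data.

## Problem sizes and robustness protocol

The package's standard experiments use the 100-tree `default10` forest
(~5k points/tree). The robustness protocol fixes one base forest, then per
repeat redraws uniform decimation to 10% of points and uniform random
vertical-axis rotations, 10 repeats per arm, comparing median ARI to the
full-density baseline; medians stay within 0.1 of the baseline in both arms.
Decimation to 1% at this scale leaves ~50 points per tree — below the
occupancy density at which voxel features carry signal — so stability down to
1% is only meaningful for much larger clouds than the simulated ones; this is
a scale effect of the generator, not a property of the method.

Voxel sizes $\delta \in \{0.125, 0.25, 0.5, 1, 2\}$ m are supported; very
coarse grids (2 m) obscure crown detail and degrade agreement, very fine ones
amplify sparseness, which the robustness driver demonstrates directly.

## A worked example

```{r example, eval = FALSE}
forest <- simulate_forest("default10", n_per_species = 10, seed = 1)
run <- run_pipeline(forest, delta = 0.5, alpha = 2, beta = 0.1, vote_k = 1)
glance(run$communities)
run$agreement
autoplot(run$communities,
         species = setNames(forest$species, forest$tree_id))
```

Ablations run through `feature_subset` (`build_tree_graph()`,
`run_pipeline()`), parameter studies through `sweep_alpha_beta()`, and
robustness studies through `robustness_experiment()` with
`plot_robustness()`.

## Known limitations

* Absolute crown size enters only through f1; two species with identical
  profile shapes at different scales are hard to distinguish by design
  (rotation- and density-robust descriptors trade this away).
* Greedy modularity optimisation inherits the resolution limit: many small,
  equally similar species in one forest can merge. Raising $\alpha$ or
  $\beta$ splits them, at the price of fragmenting heterogeneous species.
* The feature JSON importer (`read_feature_json(strict = FALSE)`) is a
  best-effort reader for externally produced files; schemas other than the
  package's own may need adaptation.
* LAS/LAZ input requires the optional `lidR` package at runtime; XYZ and PLY
  are always available.
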