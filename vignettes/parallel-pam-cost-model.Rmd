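---
title: "Parallel PAM and its operation-count cost model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel PAM and its operation-count cost model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parapam)
library(dplyr)
```

## The model

PAM partitions N points x_1..x_N (d real attributes each) into K clusters
represented by medoids m_1..m_K, themselves data points, minimising the
objective

Cost = Σ_i min_j D(x_i, m_j),

where D is a point-to-point metric (Euclidean by default). The algorithm has
two phases, implemented here exactly as the classical pseudo-code describes
them:

* **Build.** K greedy rounds. In round k every active non-medoid point is
  scored as Σ_i min(distance of x_i to the k−1 chosen medoids, distance of
  x_i to the candidate); the minimiser joins the medoid set. Round 1 thus
  selects the most central point of the data.
* **Swap.** Repeat: (1) tag every point with its nearest medoid; (2) within
  each cluster, the member with the smallest sum of distances to all members
  becomes the new medoid. Stop when no medoid changes. Note the candidate
  pool for step (2) is restricted to *members of the same cluster* — this
  variant, not the Kaufman–Rousseeuw swap over all (medoid, non-medoid)
  pairs, is what the package implements, because it is the form that
  decomposes cleanly across processing elements.

Because step (2) minimises the within-cluster sums given the tags and step
(1) minimises the cost given the medoids, the objective is non-increasing
across swap iterations and the algorithm terminates on every finite input.
Both facts are asserted as property tests.

### Parallel decomposition

The parallel engine simulates P homogeneous processing elements (PEs)
executing synchronous rounds with PE 1 as master:

1. The dataset is padded with inactive records to the smallest length
   divisible by P and split into P contiguous equal blocks. Padding records
   are *computationally inert*: never candidates, never charged, tagged NA.
   (Padding with literal zero points would change the clustering; inert
   padding preserves exactness.)
2. Build rounds: each PE scans only its block's candidates, each scored
   against all N active points; the master takes the global argmin of the
   per-PE bests and broadcasts the new medoid.
3. Swap rounds: each PE tags its block, broadcasts the block's tags (so
   every PE holds the full clustering), scores its block's members of each
   cluster against all of that cluster's members, and sends per-cluster
   bests; the master selects per-cluster global argmins and broadcasts the
   updated medoids. Empty clusters keep their medoid.

Every tie — build score, nearest medoid, update sum — breaks to the lowest
point (or medoid position) index. That single rule makes the decomposition
*exact*: for every P, the parallel run returns bit-identical medoids, tags,
cost and iteration count to the sequential run. The test suite checks this
on over a hundred seeded instances across metrics, initialisations and
non-dividing P, and once at N = 400 across P = 1..64.

The simulation is deliberately sequential-deterministic (a loop over PEs
inside a loop over rounds): the quantities of interest are operation counts,
not wall-clock time, and determinism makes the equivalence contract testable
exactly. A genuinely concurrent backend would have to honour the same
contract.

## The cost ledger

The running-time model charges the **literal pseudo-code loops**, not the
optimised implementation (the kernels vectorise and reuse nearest-chosen
distances; the ledger models the canonical execution that recomputes them):

* one pairwise distance between d-dimensional points = **d scalar units**;
  comparisons, sums of charged terms, and square roots are free;
* build round k charges (N−k+1)·N·k distance evaluations, i.e. the d-unit
  convention gives the closed form `expected_build_units(n, k, d)` =
  d·Σ_k (N−k+1)·N·k;
* each swap iteration charges N·K distances for assignment and Σ_j n_j² for
  the update (self-distances included, as the loops are written);
* communication (parallel only, charged once per message on the shared
  bus): a per-PE candidate/update best is 2 units (sum, index), a tag block
  is its block size, a medoid broadcast is 1+d units per medoid. Every PE
  sends its message each round even when it holds no eligible candidate
  (an empty marker), so one swap iteration costs exactly
  N + 2KP + K(1+d) units.

Sequential running time n1 is the total compute charge. Parallel running
time np is the **critical path**: the per-round maximum over PEs, summed
over rounds, plus all communication. Speedup is S_p = n1/np. In
`speedup_sweep()` the P = 1 row *is* the sequential reference (np = n1,
S_1 = 1): a single element running the sequential algorithm has nobody to
talk to. The parallel engine can still be forced to run its full protocol on
one element (`engine = "parallel", pes = 1`), in which case its critical
path is n1 plus the protocol's communication — both conventions are tested.

Two consequences the acceptance checks quantify at the reference
configuration (N = 800, d = 2, K = 4, uniform random points, five seeds):
the total sequential charge lands near 1.4×10⁷ units (the build phase
contributes a fixed 12,768,000; swap iterations add the stochastic rest),
and the per-PE critical path (communication excluded) halves and quarters at
P = 2 and P = 4. Build-phase units are conserved exactly across PEs for any
P, since the candidate blocks partition the candidate set.

Because compute grows as N² and communication as N, speedup curves bend
toward the ideal line as N grows; with random initialisation (no build
phase) the fixed communication weighs more and speedup is lower. Both
orderings are asserted over seeds rather than read off a figure.

## Choice of metric

Euclidean distance (with the square root) is the default and the form used
in the objective; squared Euclidean and city block are provided as
alternatives. The unit charge is d per distance *regardless of metric*, so
whenever two metrics produce the same assignment trajectory and iteration
count the ledgers — and therefore the speedup curves — are identical. The
test fixes this with well-separated Gaussian blobs, where the trajectories
coincide (the medoid chosen *inside* a tight blob may still differ between
metrics; the charges cannot).

## Segmentation and SSIM

`segment_image()` flattens an H×W RGB raster row-major into an N×3 point
set (N = H·W), clusters it, and recolours every pixel with its cluster
medoid's colour — so the output palette has at most K colours, all of them
actual input pixels. The parallel and sequential engines produce
byte-identical rasters; the acceptance check expresses this as SSIM = 1 on
a 90×108 (9720-pixel) four-region synthetic image at P = 64 vs P = 1.

SSIM is implemented with the canonical constants: 11×11 Gaussian window
(σ = 1.5, radius 5), C1 = (0.01·255)², C2 = (0.03·255)², statistics as
weighted moments without sample-covariance correction, the map averaged over
fully interior window positions, channels averaged equally. Two independent
anchors pin the implementation in the tests: the closed form for constant
images (variances vanish, leaving the luminance term), and a value frozen
from scikit-image's `structural_similarity` (gaussian_weights, σ = 1.5,
`use_sample_covariance = FALSE`, data_range 255) on a deterministic
pattern, which agrees to 1e−6. Equivalence between the engines is
parameter-independent (identical rasters give 1 under any SSIM variant).

## Synthetic data: what it does and does not show

Three seeded, pure generators make every experiment self-contained:

* `gen_random_points()` — i.i.d. uniform points on a box, defaults d = 2
  and the N = 400–1600 range of the scalability experiments. Used for the
  operation-count and speedup checks.
* `gen_gaussian_clusters()` — K spherical blobs with centres at mutual
  distance ≥ `separation`, per-cluster sizes `round(N·weights)` (residual to
  cluster 1). Equal weights give the balanced-cluster condition, skewed
  weights the unbalanced one. Points are emitted grouped by cluster — the
  deliberate analogue of the spatial coherence of image pixels — because
  under contiguous blocks that is precisely what makes cluster imbalance
  visible in the swap phase: the PEs holding the large cluster's span do
  (local members)·n_j work while others idle, so balanced clusters give
  better swap-phase speedup. Shuffled input would hide the effect behind
  sampling noise.
* `gen_synthetic_image()` — K vertical flat-colour bands from a fixed
  well-separated palette, optional bounded integer noise. At noise 0 the
  image has exactly K colours, so segmenting with matching K must reproduce
  the input exactly (and does, which is itself a test).

Passing these tests shows the algorithm, the decomposition and the cost
model are internally correct and reproduce the reference operation counts
under the stated input model. It does *not* show anything about clustering
quality on real images (real medical rasters have texture, gradients and
compression artifacts; only lossless inputs keep the pixel multiset intact,
hence the warning on JPEG input) nor about wall-clock speed on real
hardware, where memory bandwidth and interconnect contention are not part
of the unit model.

## Numerical and design choices

* **Indexing.** Rows, medoid ids and blocks are 1-based throughout, the R
  idiom; cluster tags run 1..K.
* **Tie-breaks.** Lowest index everywhere, as above; `which.min` on
  ascending candidate vectors implements it directly.
* **Convergence.** The stop test is exact equality of the per-cluster
  medoid vectors between consecutive iterations; `swap_iterations` counts
  executed assign+update rounds including the final confirming one, so the
  minimum is 1 (e.g. K = N). `max_iter` defaults to 100 as a guard against
  pathological floating-point oscillation; monotonicity makes it
  unreachable in practice, and hitting it flags the fit rather than
  erroring.
* **Exactness of the equivalence.** Both engines route every distance
  through the same compiled kernel with a fixed accumulation order over
  attributes, and per-candidate scores are column-independent, so chunking
  by PE block cannot change a single bit.
* **Memory.** Distances are computed on demand; no N×N matrix is ever
  formed (O(N·d) memory), which is what makes the 9720-pixel image runs
  cheap.
* **Degenerate inputs.** Duplicate points are kept (duplicate medoids can
  then own empty clusters, which retain their medoid); K = N is legal and
  converges in one iteration with cost 0; P must not exceed N so every PE
  holds at least one real record.
* **Problem sizes.** The suite runs at N ≤ 1600 for point sets and up to
  9720 pixels for images — the scales at which the reference counts are
  defined — and finishes in well under a minute for the acceptance
  segmentation pair.

## Limitations

* The swap phase is the within-cluster variant (see above), not the full
  pairwise swap of the original PAM; results can differ from
  `cluster::pam()` on data where a cross-cluster swap would help.
* The communication model is bus-like (one charge per broadcast) with a
  stated per-message unit convention; other interconnects (point-to-point,
  NoC) would change the overhead term, though not its Θ(N) scaling.
* CLARA/CLARANS-style subsampling, categorical/Gower distances, and spatial
  regularisation of segmentations are out of scope.
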