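---
title: "Craniometric population affinity with CranioNet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Craniometric population affinity with CranioNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CranioNet)
```

## The problem

Biodistance analysis treats quantified phenotypic dissimilarity between
skeletal samples as a proxy for population relationships. CranioNet
implements a complete distance-based pipeline for cranial measurements in
Martin's osteometric system: population samples are summarised by
per-measurement means, standardized against a common reference, compared by
Q-mode correlation, and the resulting `1 - r` distances are displayed as a
NeighborNet split network; a parallel PCA of the standardized means
separates overall cranial size from shape contrasts and lets single ancient
crania be projected onto axes fitted from modern comparative samples.

The working battery is the thirteen most consistently available
measurements on fragmentary crania (`martinBattery()`): maximum cranial
length and breadth (M1, M8), minimum/maximum frontal breadth (M9, M10),
basion-bregma height (M17), upper facial breadth (M43), bizygomatic breadth
(M45), bimaxillary breadth (M46), upper facial height (M48), orbital
breadth/height (M51, M52) and nasal breadth/height (M54, M55), all in mm.

## Data model

Two containers cover the field's two table shapes. `CranialSpecimen` holds
one individual's measurements with per-value flags: `observed`, or
`estimated` for values reconstructed from preserved parts or predicted by
regression (rendered in parentheses in the CSV dialect, as in the published
tables). `PopulationSample` holds a named group's per-measurement `n`, mean
and sample SD (n - 1 denominator, consistent with how SDs are reported for
groups of 3-6 crania); a measurement seen in a single individual carries no
SD. Estimated values participate in aggregation and all downstream
computation by default — the source tables use parenthesised values in
their battery — and `includeEstimated = FALSE` excludes them.

One regression imputer ships with the package:
`M17 = 1.05 * ABH + 14.26` (mm), estimating basion-bregma height from
auricular-basion height. It is the sanctioned fill-in for the one battery
measurement that is frequently unobservable on fragmentary vaults;
`imputeM17(112)` returns 131.86, rounded to 132 for reporting.

The packaged fixture `loadFocalCrania()` transcribes the published female
measurement table for seven focal sites: five single crania (Yahuai, Hang
Cho, Mai Da Dieu, Bau Du, Xiaoma) and two summary samples (Huiyaotian,
Liyupo). One transcription judgement call: the bimaxillary-breadth row
prints a stray minus sign before one value; a negative breadth being
physically impossible, the value is stored as positive with an `estimated`
flag.

## Standardization and the Q-mode correlation distance

Population mean profiles are z-scored measurement-wise,

$$z_c = \frac{\bar{x}_c - g_c}{s_c},$$

where $g_c$ is the grand mean of the comparative samples' means for
measurement $c$ and $s_c$ is the SD donated by a single reference sample
(the Jomon role in the motivating analysis). Two deliberate choices:

* **Unweighted grand means.** Each comparative sample's mean counts once,
  regardless of its n. Comparative sample sizes differ by orders of
  magnitude for arbitrary curatorial reasons; n-weighting would let a few
  large series define the origin.
* **Held-out samples never enter the grand mean.** Focal/ancient samples
  are standardized against the comparative reference but excluded from it,
  so adding an ancient specimen cannot move the coordinate system.

The similarity between two profiles is the Pearson product-moment
correlation computed *across* the 13 battery values (Q-mode: objects
correlated over variables). The conventional, mean-centred Pearson form is
used rather than an uncentred cosine — the standard reading of "Q-mode
correlation coefficient" in the biodistance literature. The distance is
`1 - r`, so it lives in [0, 2]; values above 1 (negative correlation) are
not clipped, since the network construction downstream tolerates them. A
profile with zero variance across the battery has no defined correlation
and is rejected with its sample id. Samples missing any battery code are
rejected rather than silently pairwise-deleted: the battery was chosen to
be completable, and imputation is the explicit repair path.

## NeighborNet

`neighborNetOrder()` implements the agglomerative circular-ordering
algorithm of Bryant & Moulton (2004). Clusters start as singletons and hold
one or two *active nodes* (the endpoints of a growing path of taxa).
Iteratively:

1. **Cluster selection.** With cluster distances $D(A,B)$ the average of
   inter-node distances, choose the pair minimising the
   neighbour-joining criterion
   $(m-2)\,D(A,B) - \sum_C D(A,C) - \sum_C D(B,C)$ over the $m$ clusters.
2. **Node selection.** Among endpoint pairs $x \in A$, $y \in B$, minimise
   the same criterion evaluated with $x$ and $y$ as singletons alongside
   the remaining clusters.
3. **Reduction.** Orient the two paths so $x$ and $y$ are adjacent and
   repeatedly replace the leading three consecutive nodes $(x, y, z)$ by
   two, using the equal-thirds formulas
   $d(u,a) = \tfrac{2}{3}d(x,a) + \tfrac{1}{3}d(y,a)$,
   $d(v,a) = \tfrac{2}{3}d(z,a) + \tfrac{1}{3}d(y,a)$,
   $d(u,v) = \tfrac{1}{3}\{d(x,y) + d(x,z) + d(y,z)\}$,
   the canonical parameterisation of the published method.

When one cluster remains, its path is the circular ordering. Both selection
steps break ties by the lowest index pair in a fixed column-major scan, so
the ordering is deterministic — reconstruction runs are byte-identical. The
returned cycle is canonicalised (rotated to start at taxon 1, reflected so
the second element is smaller than the last); a circular ordering is only
defined up to rotation and reflection, and the canonical form makes
regression tests stable.

`estimateSplitWeights()` then solves
$\min_w \lVert d - \sum_s w_s\,\delta_s\rVert^2$ over all $n(n-1)/2$
interval splits of the ordering, where $\delta_s$ indicates whether a taxon
pair is separated by split $s$. Non-negativity ($w_s \ge 0$, the default)
is enforced by a Lawson-Hanson active-set solver
(`pracma::lsqnonneg`), reached only when the unconstrained least-squares
solution is infeasible. Splits with weight at or below `1e-8` are dropped —
mirroring standard practice of discarding negligible splits — except
trivial (singleton) splits, which are retained because they carry the
terminal edge lengths of the drawn network. On an additive tree metric the
positive non-trivial splits coincide with the tree's bipartitions and the
fit residual is zero, which is how the method generalises neighbour
joining; the test suite asserts exactly this against `ape::nj` and an
independent NeighborNet ordering implementation on random tree metrics.

`writeNexusSplits()` emits a TAXA block plus a SPLITS block in the
SplitsTree 4 dialect (`CYCLE` with 1-based indices, one `MATRIX` line per
split with weight and member indices, splits ordered by weight descending
then lexicographically), so networks can be drawn in SplitsTree;
`readNexusSplits()` round-trips the file. Planar layout itself is out of
scope. `writeDistancePhylip()`/`readDistancePhylip()` provide PHYLIP square
matrices with 10-character label sanitisation and collision suffixing.

## PCA with held-out projection

`fitPCA()` eigendecomposes the covariance matrix of the fit-set
standardized profiles, centred on fit-set means. No second per-variable
rescaling is applied: the profiles are already standardized by the
reference SDs, and correlation-matrix PCA would silently erase that choice.
Three conventions:

* **Sign.** Each eigenvector is flipped if its loading sum is negative, so
  a shared size axis appears as PC1 with positive loadings — the natural
  reading of craniometric PCAs — and eigenvector sign indeterminacy cannot
  flake regression tests.
* **Retention.** `retainedComponents()` implements both published rules —
  eigenvalue strictly greater than 1 (Kaiser) and contribution strictly
  greater than 10% — with strict inequalities ("greater than").
* **Centering.** Scores are centred on the *fit-set* means (not on the
  grand means of the Q-mode standardization); whether the two origins
  coincide is unknowable from the motivating text, and fit-set centering
  guarantees exactly zero-mean fitted scores.

`projectProfiles()` maps any complete profile onto the fitted axes
(`t(L) (z - center)`) without altering the model, so single ancient crania
are scored against modern axes. Projected singletons carry roughly the
within-population dispersion (about one z-unit per coordinate), several
times the dispersion of fitted population means — they scatter around their
cluster's centroid rather than inside the tight hull of population means,
which is why the test suite asserts nearest-centroid assignment in the
PC2/PC3 plane rather than hull membership.

## The synthetic generator

`generatorConfig()`/`generatePanel()` produce panels with exactly the
statistical structure the analysis assumes, so every stage is testable
without any external database. Per population,

$$\mu = f \cdot (\beta + s \cdot \kappa \cdot \sigma \odot c),$$

with base means $\beta$ and within-population SDs $\sigma$ at the
magnitudes of the packaged focal-crania table (e.g. M1 about 180 mm with SD
5 mm; SDs span 1.5-5 mm), cluster sign $s = \pm 1$, contrast pattern $c$
(+1 on M1/M45/M46, -1 on M48/M55: one cluster has the longer vault, broader
face and lower upper face/nose), contrast scale $\kappa$ in within-SD
units, and a per-population size factor $f$ uniform on 0.88-1.05 (the
spread that makes small-bodied populations a visible feature of the size
axis). Individuals are independent normals per measurement; missingness is
completely at random (default 0, since the affinity chain requires complete
batteries); the reference population (default 50 individuals, contrast-free,
size factor 1) donates standardization SDs.

Defaults: 8 populations per cluster, 30 individuals per population,
$\kappa = 1$. The contrast scale is set by an identifiability budget rather
than taste: in z-units the size factor contributes variance
$\mathrm{Var}(f)\,\lVert\beta/\sigma\rVert^2 \approx 18$ along the size
direction, while a two-point contrast at scale $\kappa$ contributes
$5\kappa^2$ across its five measurements. At $\kappa = 1.5$ the two are
comparable and PC1/PC2 swap in a sizeable fraction of panels — the
generator would then contradict the size-dominance it is meant to emulate
(real craniometric series show a dominant size component). At $\kappa = 1$
size dominates (about 18 vs 5) while the clusters remain cleanly separated
in `1 - r` distance: the between-cluster z-shift is 2 per contrast
measurement against a population-mean sampling noise of
$1/\sqrt{30} \approx 0.18$.

What the generator deliberately does **not** emulate: cross-measurement
covariance beyond the shared size factor, informative missingness, temporal
drift or admixture, and sexual dimorphism. Passing the recovery tests
therefore shows the chain is correct under the model's own assumptions —
it does not validate the anthropological interpretation of any real
dataset.

## Numerical choices and degenerate inputs

* Split-weight drop threshold `1e-8`; NNLS engaged only on infeasible
  unconstrained solutions; RSS retained on the result object for
  diagnostics.
* Distance matrices are validated as finite, symmetric (to 1e-9) and
  zero-diagonal on construction; `NaN` distances and n < 4 are hard errors
  for the network stage.
* Fully tied matrices are legal: the tie-break rule makes the ordering
  deterministic, and a zero matrix yields an all-zero-weight system.
* PCA on rank-deficient data warns and returns zero trailing eigenvalues;
  fit sets not larger than the battery warn.
* Degenerate (zero-variance) profiles, incomplete batteries, duplicate
  ids, malformed cells and non-positive reference SDs all fail fast with
  the offending sample/measurement named.

## Test-suite problem sizes

The suite runs entirely on generated data at desk scale: tree-oracle
comparisons on 50 random additive metrics of 5-8 taxa; planted circular
split systems of 6-9 taxa; cluster-recovery and PCA-recovery simulations
over 100 seeded replicates of the default 16-population panel; affinity
properties over 100 replicates of reduced panels (4-5 populations per
cluster, 10-15 individuals). `scripts/acceptance.R` recomputes the same
headline quantities from scratch with a caller-supplied seed.

## Limitations

The package reproduces a specific analytical tradition — Q-mode
correlation on standardized means, NeighborNet, covariance PCA — and
intentionally omits alternatives a practitioner might also want:
Mahalanobis D² distances, size-correction by row-wise centring, bootstrap
support for splits, and PCA rotations. The 67-population worldwide
comparative database used in the motivating analysis is not
redistributable here, so the published retention structure of that PCA
(five eigenvalues above 1, cumulative contribution 85.64%, four components
above 10%) is expressed as a test that runs only when a user supplies that
table; it fails visibly otherwise rather than pretending to verify it.
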