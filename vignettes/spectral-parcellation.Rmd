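---
title: "Spectral parcellation of cortical surfaces: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral parcellation of cortical surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A cortical hemisphere, represented as a closed genus-0 triangle mesh, can be
partitioned into a handful of lobar-scale regions using nothing but its
geometry.  The key observation is that the low-frequency eigenfunctions of
the Laplace-Beltrami operator — the surface's intrinsic Fourier modes —
encode the global shape of the hemisphere (its elongation and flattening)
while being largely insensitive to the fold pattern, and that k-means
clustering of a vertex's coordinates in this low-frequency eigenbasis yields
connected, reproducible regions whose borders track classical lobar limits.
`spanol` implements this parcellation together with its group-level
extensions, comparison metrics, a rotation-based significance test, and a
curvature-flow robustness analysis, all exercisable on synthetic surfaces.

## Model and discretization

An eigenfunction $\phi_i$ of the Laplace-Beltrami operator on a surface $S$
satisfies $-\Delta_S \phi_i = \lambda_i \phi_i$ with
$0 = \lambda_0 \le \lambda_1 \le \dots$, the eigenvalues playing the role of
squared spatial frequencies (units $1/\text{mm}^2$).  On a triangle mesh the
problem is discretized with first-order finite elements as the sparse
generalized eigenproblem $G U = \lambda M U$:

* **Stiffness** $G$: the cotangent matrix.  For the edge $ij$ shared by two
  triangles with angles $\alpha_{ij}$, $\beta_{ij}$ opposite the edge,
  $G_{ij} = -\tfrac12(\cot\alpha_{ij} + \cot\beta_{ij})$, and the diagonal
  is minus the off-diagonal row sum, so constants span the kernel.
* **Mass** $M$: the consistent P1 matrix — each triangle of area $A$
  contributes $A/6$ to its three diagonal entries and $A/12$ to its
  off-diagonal entries; `assemble_fem(lumped = TRUE)` gives the row-sum
  diagonal variant for comparison.  The consistent matrix is the default
  because it is the actual first-order Galerkin discretization; the entries
  of both matrices sum to the surface area, which tests exploit.

`compute_spectrum()` solves the pencil by shift-invert Lanczos (ARPACK via
RSpectra).  Numerical choices, all visible in the code:

* Shift $\sigma = 10^{-8}$: $G$ is exactly singular (constant kernel), so
  the factorized matrix is $G + \sigma M$, positive definite.
* The generalized problem is reduced to a standard symmetric one through a
  sparse Cholesky factor of $M$, so returned eigenvectors are
  $M$-orthonormal by construction.
* A fixed deterministic starting vector (`sin(1:n)`) and a generous Krylov
  subspace (`ncv = 4k + 1`) make runs bitwise reproducible and resolve
  eigenvalue multiplicities (a sphere's $l$-th eigenvalue has multiplicity
  $2l + 1$; with the default `ncv` the full $l = 2$ quintet is recovered).
* Each eigenvector is flipped so its largest-magnitude entry is positive —
  a deterministic convention prior to any cross-subject alignment.
* Near-degenerate eigenvalues are returned in ascending order with no
  subspace rotation; brain-like (tri-axial) shapes have simple low
  eigenvalues, and the test suite compares degenerate groups by subspace
  angles rather than column by column.
* Meshes with at most 400 vertices use a dense LAPACK solve instead.

On a unit sphere the analytic spectrum is $\lambda = l(l+1)$; the package
recovers the $l = 1$ triplet within 0.15% and the $l = 2$ quintet within
0.3% on a 2562-vertex icosphere, which the acceptance script recomputes.

## Parcellation

`spectral_parcellate()` runs k-means on the first `n_eigs_used` eigenvector
columns, *including* the trivial constant one, with no row normalization —
the eigenvector array is clustered as is.  Defaults follow the
best-performing configuration of the method: `n_eigs_used = n_clusters`
unconstrained and `n_clusters + 1` constrained, both exposed so every
eigenvector/cluster-count combination can be reproduced (the literature is
ambiguous about whether the cluster count includes the constrained region,
so both counts are caller-controlled).

k-means uses seeded k-means++ initialization with 20 restarts and keeps the
assignment with the lowest within-cluster sum of squares.  Clusters are then
renamed 1..K by decreasing size (ties by first vertex index), so repeated
runs with one seed are bitwise identical.  Cluster connectivity is *not*
enforced — k-means gives no such guarantee and none is needed on elongated
surfaces — but `enforce_connectivity()` optionally reabsorbs minority
fragments into the neighbour with the longest shared border.

**Constrained mode.**  Non-cortical vertices (the cingulate-pole analogue)
are excluded by a deliberately simple heuristic: eigenfunctions are computed
on the *whole* mesh, the constraint rows are dropped from the k-means, and
the excluded vertices receive the reserved label 0.  Dirichlet/Neumann
boundary-condition spectra are intentionally not offered; the whole-mesh
heuristic is the configuration reported to work, and a boundary-condition
spectrum would change the basis globally.

**Group mode.**  `group_spectral_parcellate()` concatenates the per-subject
eigenvector blocks row-wise and runs a single k-means, so corresponding
regions share labels across subjects with no matching step.  Because each
eigenfunction is defined only up to sign, `sign_align()` first resamples
every column on a common icosphere template (nearest-template-vertex lookup
through each subject's spherical parameterization) and flips columns whose
correlation with the reference subject (the first, by convention) is
negative.  The trivial constant column has numerically zero variance, so
its alignment uses the sign of the inner product instead of a correlation.

**Matching and consensus.**  Individual parcellations are compared on the
template through contingency tables; `match_labels()` solves the assignment
problem with the Hungarian algorithm and, among co-optimal permutations,
returns the lexicographically smallest.  `consensus()` takes a per-vertex
majority vote, ties resolved toward the smallest label.

## Comparison metrics

The **rand distance** between two partitions counts vertex pairs:
$a$ pairs co-clustered in both, $b$ pairs separated in both, and
$d = 1 - (a+b)/\binom{n}{2}$.  Both counts come from the contingency table:
$a = \sum_{kl} \binom{T_{kl}}{2}$ and
$b = \binom{n}{2} - \sum_k \binom{r_k}{2} - \sum_l \binom{c_l}{2} + a$.
A published variant of the $b$ formula
($\tfrac12\sum_{kl}(n - T_{kl})(n - T_{kl} - 1)$) is inconsistent with the
definition of $b$ — it can exceed the total number of pairs — so the
package uses the standard pair-count identity and verifies it against an
$O(n^2)$ enumeration oracle in the tests.  The distance accepts rectangular
tables ($K \ne L$) and is invariant to relabeling either side.

**Dice coefficients** $2|A \cap B| / (|A| + |B|)$ are reported per label
after Hungarian matching.  **Sulcus-boundary distances** average, over the
vertices of a sulcal line, the geodesic distance to the parcellation
boundary (vertices with an edge neighbour of a different nonzero label;
borders with the constraint label are excluded by default because they are
segmentation artifacts, not anatomy).  Distances are also expressed as a
percentage of the Fiedler-extremal geodesic — the distance between the
extrema of the first nontrivial eigenfunction, a robust proxy for the
largest geodesic extent of an elongated surface.

**Geodesics** are computed by fast marching (compiled), using the
Kimmel-Sethian planar wavefront update with its causality conditions and a
Dijkstra edge-update fallback for non-admissible (obtuse) triangle
configurations; a pure Dijkstra mode doubles as an internal cross-check.
On a 2562-vertex icosphere the antipodal distance is within 0.35% of $\pi$
while the Dijkstra bound is 5.7% off, confirming that the triangle update
carries the accuracy.  Virtual edge splitting for obtuse triangles was
considered and not implemented: the fixtures are near-equilateral and the
fallback affects only non-admissible updates.

A caveat quantified during development: because both sulcal lines and
boundaries are *vertex* sets, the measured line-to-boundary distance has a
negative bias of about one edge length (the boundary band straddles the
true interface).  On latitude-30°-to-equator sphere tests the bias is 13%,
7.4% and 3.6% of $\pi/6$ at icosphere subdivisions 4, 5 and 6, shrinking
proportionally to edge length.  Validation of this metric therefore runs at
clinical mesh resolution (subdivision 7, 163,842 vertices — the size range
of real cortical meshes), where the error is 1.8%.  On coarse fixtures the
absolute millimetre values should be read with a one-edge-length error bar.

## Significance by rotation nulls

Whether an automatic parcellation is closer to a reference map than chance
is tested against a null of independent placement: the automatic map,
living on the sphere template, is rotated by Haar-uniform random rotations
(QR of a standard normal 3×3 matrix, columns sign-corrected by the sign of
the R diagonal, determinant folded to +1 so only proper rotations are
drawn) and the rand distance to the reference is recomputed `n_rot` times
(default 500).  Rotations preserve region areas up to nearest-neighbour
resampling error (under 10% per region on the subdivision-3 template), so
null parcellations share the reference's size profile.  Labels are
categorical, so interpolation under rotation is nearest-neighbour — the
only order-0 choice.

The p-value follows the strict-inequality counting rule
$p = \#\{d_{\text{null}} < d_{\text{obs}}\}/n_{\text{rot}}$; an optional
conservative estimator $(\# + 1)/(n_{\text{rot}} + 1)$ is available, which
is the unbiased-under-null variant.  Calibration is verified by drawing the
automatic map from the null itself: across 200 replicates of 200 rotations
the p-values are uniform (Kolmogorov-Smirnov level 0.01).  The strict rule
has a slight downward tie bias (mean p ≈ 0.46-0.51 across seeds), which the
conservative estimator removes.

The test assumes a near-area-preserving spherical parameterization;
`area_distortion()` warns when the per-vertex mesh-to-sphere area ratio
spreads more than 2× around its median, as on strongly elongated
ellipsoids parameterized by raw icosphere directions.

## Mean curvature flow and stability

`mean_curvature_flow()` integrates the flow implicitly: each step solves
$(M + \mathrm{d}t\, G)\,V_{\text{new}} = M\,V_{\text{old}}$ with both
matrices reassembled on the current geometry.  Backward Euler is
unconditionally stable, so the step size only controls resolution of the
flow path; the default $\mathrm{d}t = 10^{-3}\,\bar{h}^2$ (mean edge length
$\bar h$) gives many small steps over the usual checkpoint schedules.  No
area or volume renormalization is applied during the flow (an optional
rescale exists for visualization only); area decreases monotonically, and
spheres shrink while staying spherical (radius coefficient of variation
under $10^{-3}$ after 100 steps), both checked in the tests.
`stability_curve()` re-parcellates the flowed mesh at requested checkpoints
with the same configuration and seed, Hungarian-matches the labels to the
unflowed map (the flow preserves vertex indexing, so the correspondence is
the identity) and reports rand distances — small values mean the
parcellation depends on global shape, not on the relief the flow removes.
On the standard folded-ellipsoid fixture the distances stay below 0.02 over
300 iterations, an order of magnitude below the distance to an unrelated
six-sector map.

## Synthetic study conditions

The generators provide every input the pipeline needs, with defaults chosen
once as the package's study conditions:

* `make_icosphere(s)` — the common sphere template and the closed-form test
  surface ($10 \cdot 4^s + 2$ vertices, exact parameterization).
* `make_folded_ellipsoid(axes, amplitude, frequency, subdivisions, seed)` —
  a brain-like elongated ellipsoid modulated radially by a seeded
  band-limited sum of `frequency` spherical sinusoids, normalized to unit
  peak, scaled by `amplitude` (default 0.15, about the relative relief
  amplitude of a folded hemisphere; values ≥ 1 are rejected as
  self-intersection risks).  Generation is a pure function of its
  arguments.
* `make_constraint_cap()` — a polar cap standing in for the cingulate pole
  (default half-angle 25°).
* `make_synthetic_sulcus()` — a plane-intersection curve snapped to an
  ordered edge-adjacent vertex path, standing in for manually traced
  sulcal lines.

Fixture sizes: most validation uses subdivision 3 (642 vertices) or 4
(2562); the sulcus-metric validation uses subdivision 7 (163,842) as
discussed above.  The group-consistency cohort is five folded ellipsoids
with axes (4, 1.2, 0.9), amplitude 0.1, frequency 4, differing only by
seed, clustered with K = 4.  The pronounced elongation matters: it makes
the k-means optimum shape-determined, which is the regime the group
machinery targets (real hemispheres at K = 6 behave this way).  On nearly
axisymmetric ellipsoids several cut orientations tie and group and
individual runs can legitimately select different optima — a property of
spectral clustering itself, not of the group pooling, and the reason such
shapes are not used as consistency fixtures.

What the synthetic surfaces do *not* emulate: genuine gyral/sulcal
geometry (deep folds, variable curvature sign), area-distorting spherical
parameterizations produced by registration pipelines (the synthetic
parameterization is the generating icosphere, hence mildly distorted on
elongated shapes), non-spherical topology defects, and scanner/segmentation
noise.  Passing tests therefore demonstrate correctness of the machinery
and its closed-form limits, not clinical segmentation quality.

## Conventions and limitations

* Vertex indices are 1-based inside R (the language's convention); every
  on-disk format (GIFTI, OFF, PLY, index lists, sulcal-line JSON) is
  0-based, converted at the I/O boundary.
* Meshes failing validation (open, non-manifold, genus ≠ 0) are rejected,
  never repaired: repair would change the spectrum silently.
* Exact zeros in an eigenfunction count as positive in nodal-domain
  splitting, a deterministic tie-break.
* The spherical parameterization is consumed, not computed; computing one
  (FreeSurfer's role) is out of scope.
* All pipeline randomness derives from one seed through a fixed affine
  per-stage scheme (`seed * 1000003 + stage`, mod $2^{31}-1$).
* Very high cluster counts are outside the method's regime; the spectral
  basis carries global-shape information and the approach is intended for
  lobar-scale K.
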