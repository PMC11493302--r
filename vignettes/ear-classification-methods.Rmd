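---
title: "Building and validating ear classification criterion images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating ear classification criterion images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(auriclass)
```

## The problem

The external ear varies strongly between individuals and is visible even when
much of the face is covered, which makes it useful for forensic human
identification. A morphological classification of the *whole* ear, however,
needs more than the classical part-wise typologies: it needs quantitative
prototypes that an unknown ear can be compared against. `auriclass`
implements such a system. Starting from triangle meshes of ears in dense
vertex-wise correspondence ("homologous models": every subject shares the
template's vertex count, ordering and connectivity), it

1. standardises size and posture by generalized Procrustes analysis (GPA),
2. runs a coordinate principal component analysis (PCA) over the
   `n x 3N` matrix of vertex coordinates,
3. synthesizes *composite images* (CIs) at fixed score amplitudes on single
   PCs and on all sign combinations of PC pairs,
4. reduces the CI battery by a second-stage PCA and synthesizes the final
   *classification criterion images* (CCIs) at `+/-` a fixed amplitude on
   each leading second-stage component, and
5. classifies ear meshes by assigning each to the CCI with the minimum
   *distance between vertices* (DBV), the mean Euclidean distance over
   corresponding vertices, subject to a threshold.

The upper auricle (the ear minus the lobule) and the lobule are analysed
separately throughout, because the fatty lobule is far more variable and
would otherwise dominate the prototypes. The lobule is delimited by three
landmarks: the cauda helicis, the lower incisura intertragica and the
otobasion inferius.

## Statistical model

With aligned shapes written as vectors $x_i \in \mathbb{R}^{3N}$, the PCA
model is $x_i = \bar{x} + \sum_k s_{ik}\,\phi_k + \varepsilon_i$ with
orthonormal $\phi_k$ and eigenvalues $\lambda_k$ sorted descending. We use
the population convention $\lambda_k = d_k^2/n$ (singular values $d_k$ of
the centred data matrix), so the standard deviation of component $k$ is
$\sqrt{\lambda_k}$ and "the $\pm 3$ SD shapes" are
$\bar{x} \pm 3\sqrt{\lambda_k}\,\phi_k$. Whether shape-PCA software divides
by $n$ or $n-1$ is rarely stated; `fit_shape_pca(divisor = "n-1")` switches
the convention. Contribution ratios are
$\mathrm{CR}_k = 100\,\lambda_k / \sum_j \lambda_j$ with the *full* trace in
the denominator (including components below the display cutoff), and
components are "displayed" when $\mathrm{CR}_k \ge 1\%$ by default,
mirroring the behaviour of shape-analysis packages that hide minor
components.

Three criteria decide how many components carry meaningful shape variation:

* **Scree elbow** — the component immediately before the eigenvalue curve
  turns from steep to smooth; implemented as the interior index maximising
  the second difference $\lambda_{k-1} - 2\lambda_k + \lambda_{k+1}$, minus
  one, with ties broken to the smallest index. Smooth spectra without a
  marked elbow still return the defined index.
* **EV-magnitude threshold** — the largest $m$ with $\lambda_m \ge$ a
  cutoff. On the published 414-model ear spectra shipped with the package
  (`reference_ev_table()`), cutoffs of 500 (upper auricle) and 100 (lobule)
  both cross between PC6 and PC7. We read the published "difference in EV
  was greater than 500/100 until PC6" as a magnitude threshold because the
  successive *gaps* in those tables never exceed 500/100 after PC1, whereas
  the magnitudes cross exactly at PC6 — the only reading consistent with
  the printed numbers.
* **DBV slope** — for each component, the DBV between the $-3$ SD and
  $+3$ SD shapes, which has the closed form
  $6\sqrt{\lambda_k}\cdot\frac{1}{N}\sum_i \lVert\phi_{k,i}\rVert$ for the
  mean statistic. Components past the steep drop of this curve move the
  surface too little to matter.

A fourth, cohort-size criterion asks when the *area* of shape change
stabilises: `shape_change_overlap()` compares displacement masks
(vertices whose mean-to-$+3$SD displacement exceeds a threshold) between
models fitted on nested subsets, via the Dice coefficient. The displacement
cutoff defaults to the 75th percentile of that component's per-vertex
displacements — the published renderings show "red regions" without stating
a cutoff, so the package uses a quantile rule with an absolute-mm override.
Displacement magnitudes are invariant to eigenvector sign, but the overlap
is nevertheless also evaluated against the sign-flipped component and the
larger Dice kept, as a safeguard.

## Composite and criterion images

`make_composite_images(model, k, amplitude)` synthesizes
$2k + 4\binom{k}{2}$ meshes: both signs on each single PC and all four sign
combinations on each unordered pair — 50 CIs for $k=5$, 72 for $k=6$.
Amplitudes are *raw score values* (100 for the upper auricle, 60 for the
lobule), not multiples of $\sqrt{\lambda}$: the published amplitudes are
absolute values read off score biplots, so no per-component normalisation
is applied. The second-stage PCA runs on the CI meshes without re-alignment
(they already share the model frame), and `derive_ccis()` synthesizes the
final prototypes at `+/- cci_amplitude` (100 upper, 30 lobule) on each
leading second-stage component, labelled with Roman numerals — 10 CCIs from
5 components, 12 from 6.

Classification (`classify_one`) assigns a mesh to the CCI with minimum mean
DBV when that minimum is within the threshold, and reports *all*
under-threshold labels in DBV order. Published verification of this design
included a manual step — when several CCIs fell under the threshold, the
visually most similar one was chosen. That step is not algorithmic, so the
package always assigns the DBV minimiser and keeps the full ranking
auditable for an external visual override. The threshold itself is not a
published constant; `calibrate_threshold()` sets it to the q-th percentile
(default 90) of the cohort's minimum DBVs, so about q% of the calibration
cohort classifies. Reports label it as a calibrated quantity.

Asymmetry statistics count only subjects contributing both ears; a subject
is asymmetric in a region when the left and right assignments differ
(out-of-classification differs from every label).

## Dense correspondence

Real pipelines obtain homologous models with proprietary software whose
deformation algorithm is unpublished. The package's concrete, reproducible
stand-in is:

1. closed-form similarity Procrustes (rotation, translation, scale) of the
   template onto the target using the 18 landmark pairs;
2. a 3-D thin-plate-spline warp (kernel $U(r) = r$) interpolating the
   landmark displacements, with ridge regularisation defaulting to
   $10^{-3}\times$ the target's bounding-box diagonal;
3. exact nearest-point-on-triangle projection of every warped vertex onto
   the target surface (compiled code; ties broken to the lowest face
   index for determinism);
4. optionally, `n_relax_iters` rounds of Laplacian relaxation toward the
   *warped template's differential coordinates* — each vertex is pulled to
   its neighbour mean plus the reference offset, blended with weight
   `relax_weight`, then re-projected.

Relaxation is off by default: the plain pipeline already reproduces a
target identical to the template exactly, which is the contract the test
suite pins down. The differential-coordinate form was chosen over plain
Laplacian smoothing deliberately: smoothing blended with re-projection
makes vertices drift tangentially and *degrades* the worst triangle's
aspect ratio as iterations increase, while the differential form keeps the
template's local triangle structure as the attractor, is stationary at an
identity fit, and monotonically reduces the maximum aspect-ratio
degradation on the fixtures.

Region splitting assigns each face to the region holding two of its three
vertices; the vertex sets partition the model strictly, so a straddling
face's minority corner is pinned to the face's lowest-index in-region
vertex, leaving a degenerate boundary sliver. The index maps come from the
shared template, hence are identical across subjects.

## The synthetic cohort generator

No mesh cohort is deposited with the published work, so every stage is
exercised on a synthetic population with known ground truth. The template
(`make_template`) is a parametric open sheet about 60 mm tall and 28 mm
wide with a raised helix-like rim, a concha-like depression, a tragus bump
and a lobule lobe; 18 landmarks sit on fixed parametric locations snapped
to vertices, and every vertex carries an upper-auricle/lobule label.
Resolution level 0 (600 vertices) is the desk-scale default used by the
tests; level 3 reproduces the full-scale budget of 5,507 vertices and
16,521 triangles. That budget implies three triangles per vertex, which no
manifold sheet can realise (a closed manifold has $F = 2V - 4$, an open one
fewer), so the full-scale sheet is refined by 32 centroid splits and emits
5,801 of its faces a second time reverse-wound — a two-sided region, as
surface renderers that emit both orientations produce. Vertex-wise
statistics (DBV, PCA) are unaffected by face multiplicity.

Subjects are `template + sum_k z_k phi_k + noise` with smooth orthonormal
modes (`make_modes`: seeded Gaussian fields, Laplacian-smoothed, then
orthonormalised) and $z_k \sim N(0, \sigma_k^2)$. The cohort defaults
emulate the published study conditions: 228 male subjects — 186 bilateral,
32 left-only, 10 right-only, i.e. 218 left + 196 right = 414 meshes — ages
uniform on 17–93, six modes with standard deviations 6, 5, 4, 3, 2.5, 2 mm
(a smoothly decaying mm-scale spectrum typical of facial-surface PCAs),
vertex noise 0.15 mm (surface-rendering jitter), and a 0.3 mm left/right
asymmetry perturbation added to right ears before mirroring. An optional
age-linked mode builds its scores from the standardised ages with the
residualised-noise construction, so the in-sample Pearson correlation
equals the requested value exactly. `correspondence_jitter = "resample"`
randomly permutes each target's vertex order (faces remapped), destroying
the template ordering that the fitting stage must not rely on; true
re-meshing is not attempted.

What the generator does *not* emulate: anatomical detail beyond qualitative
ear-likeness, sex differences (the reference cohort is male-only),
postmortem deformation, occlusion or partial scans, and CT reconstruction
artefacts. Passing tests therefore demonstrate the correctness and
stability of the *procedure* — counts, spectra, recovery, calibration,
determinism — not field accuracy on real CT ears; the published
cohort-level accuracy figures are not reproducible without the original
CT data.

## Numerical choices

* Eigenvector signs are fixed by making the largest-magnitude entry
  positive, so results are identical across linear-algebra backends; PCA
  uses the SVD of the centred data matrix, never the explicit
  $3N \times 3N$ covariance.
* GPA normalises every configuration (and the evolving mean) to the mean
  centroid size of the inputs, so aligned coordinates stay in mm and each
  aligned model's centroid size equals the mean's; convergence is declared
  when the mean moves by less than $10^{-8}\times$ its bounding-box
  diagonal, with a 100-iteration cap.
* CI/CCI orderings are fully deterministic (singles by PC then sign; pairs
  lexicographic with sign order $--, -+, +-, ++$), so whole-pipeline reruns
  are byte-identical.
* `cci_set_distance` matches two prototype sets by exact minimum-cost
  assignment (bitmask dynamic programming over at most $2^{12}$ states at
  these set sizes) before averaging DBVs, absorbing PC order and sign
  instability between independently fitted models.
* Subset sweeps draw nested, age-stratified subsets using the seven
  age bands of the reference cohort design (17–29 … 80–93), with default
  sizes 123, 242, 300, 363 and the full cohort.
* The published lobule CI description ("twelve … and fifty") totals 72
  only as $12 + 60$; the package implements the combinatorially forced
  $2k + 4\binom{k}{2} = 72$ at $k = 6$.

## Scale of the shipped checks

The test-suite and acceptance-script problem sizes are the package's
desk-scale design points: 600-vertex templates, cohorts of 30–60 meshes
for pipeline runs (including 414-mesh cohorts where the cohort design
itself matters), and 500 subjects for parameter-recovery checks. The
full-resolution template is generated in seconds; full-resolution cohort
runs scale linearly in vertices and are left to the user.

## Known limitations

Mean DBV is translation-sensitive and global: a mesh differing only in one
region can match a prototype worse than a uniformly offset one. The
classification threshold is a calibrated stand-in for an unpublished
constant, so under-threshold percentages track the calibration quantile by
construction on the calibration cohort. Homologous fitting assumes the 18
landmarks are correct; there is no automatic landmark detection. The
two-sided full-resolution template region is non-manifold by design and
should not be fed to tools that require manifold input.
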