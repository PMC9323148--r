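---
title: "Statistical shape modeling of craniosynostosis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modeling of craniosynostosis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniomorph)
```

Craniosynostosis — the premature fusion of one or more cranial sutures in
infants — produces characteristic head deformities: scaphocephaly (sagittal
fusion: long, narrow heads), trigonocephaly (metopic fusion: triangular
foreheads) and anterior plagiocephaly (unilateral coronal fusion: one-sided
frontal flattening). CT is the diagnostic gold standard but exposes infants
to ionizing radiation. `craniomorph` implements a radiation-free alternative
built entirely on 3D photogrammetric surface scans: dense correspondence by
template morphing, a statistical shape model by weighted PCA, and
classification of the shape coefficients.

This vignette documents the model, its assumptions, the tunable parameters,
the numerical choices, and what the synthetic test substrate does and does
not establish.

## Pipeline overview

1. **Correspondence** (`morph_scan()`): a symmetric template mesh is
   similarity-aligned to each target scan through 10 annotated landmarks
   (closed-form Procrustes with scaling), then morphed onto the target with
   optimal-step nonrigid ICP using one affine 3×4 transform per template
   vertex. After morphing, every vertex id denotes the same anatomical
   location on every scan.
2. **Mirroring** (`mirror_scan()`, `mirror_corresponded()`): each subject is
   reflected across its midsagittal plane, doubling the sample and removing
   laterality bias for the asymmetric coronal class.
3. **Shape model** (`build_shape_model()`): rigid generalized Procrustes
   alignment (translation and rotation removed; *scale kept* — head size is
   age-related signal, not nuisance), then weighted PCA through the n×n Gram
   matrix. Submodels per class and a cranium-only model are built the same
   way on their own alignments.
4. **Classification** (`classify_cohort()`): the cranial model's
   standardized coefficients feed five classifiers (SVM-RBF one-vs-one,
   LDA, Gaussian naive Bayes, 5-NN with nearest-among-tied-classes
   tie-break, decision tree) under mirror-aware stratified 10-fold CV.
5. **Applications** (`remove_pathology()`, `flexibility_modes()`): attribute
   regression in coefficient space (move a patient's coefficients along the
   difference of class means), and fixed-region flexibility modes via a
   constrained generalized eigenvalue problem.

## The weighted PCA model

Corresponded meshes are vectorized xyz-interleaved into columns of the
observation matrix $X \in \mathbb{R}^{3p \times n}$ and centered,
$X^{ZM} = X - \bar{x}$. Plain PCA would over-weight densely meshed regions
(the face); instead, a mass matrix $M$ assigns each vertex and each edge the
surface area for which it is the nearest mesh element (barycentric-cell
style), and $M_3 = M \otimes I_3$ reweights the coordinates. The model
solves the small dual eigenproblem of the weighted Gram matrix

$$G_W = (X^{ZM})^\top M_3\, X^{ZM} = U_G \Lambda_G U_G^\top,$$

then maps back to principal components $V = X^{ZM} U_G \Lambda_G^{-1/2}$
(which are $M_3$-orthonormal) and rescales eigenvalues
$\Lambda = \Lambda_G / (n-1)$. Shapes are synthesized as
$x = \bar{x} + V \Lambda^{1/2} \alpha$ with standardized coefficients
$\alpha$, and projected by the $M_3$-weighted left inverse
$\alpha = \Lambda^{-1/2} V^\top M_3 (x - \bar{x})$. Because the data are
centered, the smallest Gram eigenvalue is numerically zero and is dropped
(rank cutoff: eigenvalues below $10^{-10}\lambda_1$).

Assumptions worth keeping in mind: the coefficient distribution is treated
as multivariate normal, which cannot be literally true for a training set
that mixes four diagnostic classes; for classification the model acts as an
area-aware re-parameterization and dimensionality reduction, which is all
that is required. Whether projection should use the $M_3$-weighted or the
plain least-squares inverse is a genuine design choice; the weighted inverse
is used because it is the exact left inverse under the model's own inner
product.

### Numerical conventions

- Eigenvector signs are fixed by making each component's largest-magnitude
  entry positive, so repeated builds are bit-identical.
- The mass-matrix face partition uses a deterministic barycentric grid
  (subdivision 20, 231 samples/face) classified by nearest element *center*
  (vertex or edge midpoint), ties broken in a fixed candidate order. A
  naive nearest-element rule with edge *segments* would be degenerate —
  a segment contains its endpoints, so an edge is always at least as close
  as a vertex and the diagonal collapses. Because edge regions outweigh
  vertex regions, the raw vertex/edge matrix is indefinite, while the model
  needs a PSD metric (real eigenvalue square roots, complete component
  basis); each face's edge mass is therefore partially lumped onto its
  endpoint vertices, by the largest per-face factor that makes the face
  block diagonally dominant. This conserves each face's area exactly and
  keeps all weights area-derived.
- GPA stops when the relative mean-shape change drops below 1e-7
  (max 100 iterations); the Euclidean metric is used throughout.
- The `(n-1)` eigenvalue denominator applies to whatever `n` a (sub)model is
  built from.

## Nonrigid ICP morphing

The morph minimizes, at each stiffness level, the sum of (i) a stiffness
term $\alpha\,\|(M_e \otimes G)\,X\|^2_F$ penalizing transform differences
across template edges with $G = \mathrm{diag}(1,1,1,\gamma)$, (ii) a
distance term pulling each transformed vertex to its closest point on the
target surface (point-to-triangle, exact), and (iii) a landmark term. All
three are linear in the stacked transforms $X \in \mathbb{R}^{4p \times 3}$,
so each iteration is one sparse normal-equation solve. Correspondences whose
normal angle exceeds 90° or whose distance exceeds 10× the target's median
edge length get zero weight (guards against holes and clothing artifacts in
real scans).

Defaults (all configurable via `nicp_config()`): stiffness 100→1 in 8
geometric steps; landmark weight decaying linearly 10→0 so landmarks guide
the stiff global phase and release for the detail phase; $\gamma = 1$;
per-level convergence when the transform-change Frobenius norm falls below
$10^{-4} p$; at most 20 inner iterations per level.

Template-side landmarks are embedded **barycentrically** in their containing
template face rather than snapped to the nearest vertex. On coarse templates
the nearest vertex can sit several mm from the anatomical point, and a
vertex-anchored landmark term then drags the surface tangentially; the
embedded constraint is consistent at any resolution.

Mirrored observations are obtained by reflecting the morphed template across
the subject's midsagittal plane and composing with the template's exact
bilateral vertex symmetry permutation. For a symmetric template this is the
mirror-equivariant image of the same morph, at no extra cost; morphing the
reflected scan directly gives the same corresponded surface.

## Mirror-aware cross-validation

Folds are stratified over the *unmirrored* scans only; each fold's training
set is the remaining originals plus the mirrors of those originals. A test
subject's mirror twin therefore never appears in training (its near-identical
geometry would leak label information), yet training still benefits from the
doubled, symmetry-balanced sample. The pooled confusion matrix tests each
original exactly once. These invariants are asserted programmatically on
every plan construction and every CV run.

A single global cranial model projects all scans (per-fold model rebuilds
are available via `build_cranial_model()` on the fold's training columns,
but the default matches extracting one coefficient vector per observation
from one cranial model). Note that the shape model itself is unsupervised;
only the classifier sees labels.

## The synthetic cohort

No patient scans can be redistributed, so `generate_head()` provides a
seeded, fully analytic substitute: a subdivided-icosahedron ellipsoid
(half-axes 55×72×65 mm, ~2.5k vertices at the default subdivision 4,
configurable down for fast tests) with

- a frontal face protrusion (amplitude per subject, U(4,14) mm) kept below
  the cranial vault,
- five mirror-paired facial-detail factors (nose, chin, cheeks, ears, neck;
  sd 1.5 mm) giving individual facial variation independent of the cranium —
  the variation that fixed-cranium flexibility modes are meant to recover,
- class deformity fields following the clinical growth patterns (restricted
  growth perpendicular to the fused suture, compensatory growth along it):
  sagittal = anteroposterior elongation with lateral narrowing (exact
  length/width ratio factor $1+m$); metopic = an anterior wedge narrowing
  the forehead; coronal = unilateral frontal flattening with a contralateral
  bulge *plus* a mild brachycephalic AP shortening ($\sqrt{1+0.5m}$) — the
  symmetric component matters, because after mirror augmentation a purely
  antisymmetric deformity would be linearly inseparable from symmetric
  controls; control = small mirror-symmetric random bumps,
- global size U(0.85, 1.15) emulating age, deformity magnitudes U(0.2, 0.4),
  and i.i.d. Gaussian vertex noise (default 0.5 mm, photogrammetry-scale).

Landmarks are placed by the same analytic map and then projected onto the
generated mesh surface, as an expert annotates on the scan itself. All draws
are seed-deterministic.

What the synthetic cohort does *not* emulate: real anatomy (it is a smooth
genus-0 proxy, no ears/neck geometry beyond bumps), scanning artifacts
(holes, clothing, isolated parts), age-shape covariation beyond uniform
scale, and the clinical boundary cases (mild plagiocephaly in the control
group). Passing the end-to-end recovery check therefore demonstrates that
the pipeline's machinery — morphing, area-weighted dual PCA, leakage-free
CV, classifiers — is correct and recovers constructed class structure
through the full chain; it does not certify clinical accuracy on real
patients, whose published headline numbers require the original cohort.

### Problem sizes

The shipped checks run the full chain at reduced resolution, chosen so the
whole suite completes comfortably on one CPU: a 162-vertex template morphed
onto 642-vertex scans, 40 scans/class (seed 7, doubled to 320 by
mirroring), LDA on the first 10 cranial coefficients. Model-metric and
application checks use 20-shape cohorts at 162 vertices. At these sizes the
end-to-end LDA accuracy check (≥ 0.90) leaves a wide margin in practice.

## Fixed-cranium flexibility modes

With $S = V\Lambda^{1/2}$, split rows into free coordinates $A$ and fixed
coordinates $B$ (e.g. the cranial mask). Directions that move the free
region most per unit fixed-region motion solve

$$(A^\top A)\,w = \lambda\,(B^\top B + \varepsilon I)\,w,$$

solved by Cholesky reduction to a symmetric eigenproblem; modes come out
$(B^\top B + \varepsilon I)$-orthonormal with descending $\lambda \ge 0$.
The Tikhonov floor $\varepsilon = 10^{-8}\,\mathrm{tr}(B^\top B)/m$ keeps
the pencil definite when $B^\top B$ is rank-deficient (the exact
numerator/denominator convention of the constrained formulation is a design
choice made here and flagged as such). Two structural facts determine what
this can achieve:

- After GPA, any localized variation direction carries a global rigid
  compensation, so a model needs several independent non-cranial factors
  before a combination with (near-)zero cranial displacement exists. The
  construction check therefore uses a noise-free cohort whose only variation
  is facial and global size; there the mode-1 fixed/free RMS ratio is ~1e-5.
- With measurement noise and per-subject idiosyncratic cranial variation in
  the training set, every component carries some cranial energy and the
  achievable ratio degrades gracefully (tens of percent on small noisy
  cohorts); that is a property of the data span, not of the solver.

`remove_pathology()` is a pure translation in coefficient space
($\alpha' = \alpha + \alpha_{\mu,\mathrm{to}} - \alpha_{\mu,\mathrm{from}}$),
hence exactly invertible; class means are computed by projecting each
class's aligned training shapes into the full model and averaging.

## Evaluation metrics

Morphing is scored by landmark error (mean distance between morphed
template landmark vertices and annotated targets), vertex-to-nearest-
neighbor distance (mean exact point-to-triangle distance to the target), and
per-class surface-normal deviation (classes are GPA-aligned separately so
genuine between-class shape differences are not counted as correspondence
error; the cumulative value is the sample-size-weighted class average).
Model quality uses the standard triple: compactness (cumulative eigenvalue
fraction), generalization (leave-one-out reconstruction error, mean
per-vertex mm — the mean rather than RMS convention is used and documented),
and specificity (mean per-vertex distance from Gaussian samples to the
nearest training shape; corresponded topologies make per-vertex distance
meaningful).

## Known limitations

- The morphing system solves dense normal equations per stiffness level;
  for the 13k-vertex templates of clinical practice a few seconds per scan
  is expected, and the brute-force closest-point kernel, while compiled, is
  O(p·t) — a spatial index would be the next step for large cohorts.
- The cranial mask default (vertices above the euryon level) is a
  geometric stand-in for an anatomically curated mask.
- Landmark schema is configurable but defaults to a 10-point set (nasion,
  sellion, exocanthia, tragi, eurya, opisthocranion, vertex point); any
  schema with ≥3 midline points and matched left/right pairs works.
- The LBRP/ICPD morphing alternatives, texture modeling, probabilistic PCA
  and Gaussian-process morphable models are out of scope.
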