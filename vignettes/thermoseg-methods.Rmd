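---
title: "Curvature-initialized GVF segmentation and asymmetry classification of breast thermograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-initialized GVF segmentation and asymmetry classification of breast thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(thermoseg)
```

## The problem

Frontal breast thermograms encode skin temperature as pseudo-colour.
Malignant tissue is metabolically hotter than its surroundings, so an
abnormal breast tends to show a localized hot spot and, crucially, a
*bilateral asymmetry*: the two breasts of a healthy subject are close to
mirror images in shape, colour and texture, while disease breaks the
symmetry.  `thermoseg` implements a complete desk-scale pipeline around
this idea:

1. **Silhouette analysis.** The gray image is denoised (3 × 3 Gaussian)
   and thresholded at 0.25; the body silhouette's left and right margins
   are traced as closed pixel curves.
2. **Curvature-based initialization.** Along each margin the signed
   curvature function `k = (x''y' − x'y'') / (x'² + y'²)^{3/2}` (the rate
   of change of the tangent angle with arc length) is evaluated on
   Gaussian-smoothed coordinates.  The junctions where a breast's
   elliptical arc meets the chest wall are sharp curvature extrema; those
   delimiting peaks select the margin arc to which a direct least-squares
   ellipse is fitted, and the ellipse — uniformly contracted — becomes the
   initial snake.
3. **GVF snake.** A Gradient Vector Flow field is diffused from the edge
   map of the gray image and a closed active contour evolves under
   elasticity, rigidity and the GVF force until it locks onto the breast
   boundary.  The converged contours are rasterized into per-breast
   masks.
4. **Feature extraction.** Each breast region yields 4 shape
   descriptors, 5 first-order statistics × 3 colour channels and 4
   co-occurrence (GLCM) statistics × 3 channels; every left/right pair of
   these 31 base features additionally yields 3 asymmetry distances.  In
   total 8 + 30 + 24 + 93 = 155 named features per image.
5. **Classification.** A small convolutional network consumes the
   segmented image directly; a random forest, a multilayer perceptron and
   a naive Bayes model consume the feature vector.  All are evaluated by
   stratified 2-fold cross-validation with the full indicator set (TPR,
   PPV, FDR, F1/HM, SPC, NPV, ACC, FPR, rank AUC).  Segmentation quality
   against reference masks is measured by the Zijdenbos Similarity Index
   (ZSI), identical to the Dice coefficient; values above 0.75 are
   conventionally "excellent agreement".

Everything is testable without any data download through a seeded
synthetic phantom generator.

## Orientation and sign conventions

Curvature signs are meaningless until the traversal convention is fixed.
The package stores pixel coordinates 0-based with x = column and y = row
(y pointing down), and defines "counter-clockwise" as seen on screen.  A
convex curve traversed counter-clockwise on screen has positive `k`
under the formula above (a circle gives `k = +1/r`), and reversing the
traversal flips the sign pointwise — both facts are asserted in the test
suite.

`extract_margins()` orients the left-half margin counter-clockwise and
the right-half margin clockwise.  With that pairing the concave
breast/chest-wall junction corners — the salient points that delimit each
breast — appear as *negative minima* on the left margin and *positive
maxima* on the right margin, which is exactly what
`find_curvature_peaks()` looks for on each side.

## Peak detection and elliptical initialization

A point qualifies as a delimiting peak only if it exceeds
`min_prominence` (default 0.005 px⁻¹) both in absolute curvature and in
topographic prominence.  The double requirement is deliberate: absolute
height alone would flag every point of a small circle (constant large
`k`, no local structure), while prominence alone would flag numerical
ripples on straight stretches that happen to neighbour deep valleys.

Given the candidate peaks, `fit_initial_ellipse()` considers *every*
peak pair and both arcs each pair delimits, fits a direct least-squares
conic constrained to ellipses to each candidate arc, and keeps the
best-fitting ellipse among arcs covering at least 25 % of the margin.
The exhaustive pair search makes initialization robust to duplicate
peaks detected on the same junction corner; degenerate conics (e.g.
collinear arcs) are rejected rather than silently replaced by a circle.
If fewer than two peaks are found, the fallback takes the two
extreme-curvature points of the correct sign, forced at least a tenth of
the margin apart.

The fitted ellipse is contracted by a uniform radial factor before snake
evolution.  The pipeline default is **0.90** rather than a more timid
0.95: the thresholded silhouette boundary lies one to two pixels
*outside* the luminous edge (the threshold crosses the soft edge profile
below its midpoint), so the fitted ellipse is slightly oversized, and a
0.95 contraction can start vertices outside the breast near the
junction, where they are free to leak along the chest-wall edge.  The
GVF capture range makes the extra contraction costless — phantom tests
recover the boundary from initial scalings 0.8–1.1.

## Edge map, GVF field and snake dynamics

The external energy is the classic three-term combination on the
smoothed gray image `I_s = G_σ * I`:

* line term `w_line · I_s` (attraction toward warm/bright regions),
* edge term `w_edge · |∇I_s|²`,
* termination term `w_term ·` curvature of the level lines of `I_s`,

with weights `w_line = 0.01`, `w_edge = 0.40`, `w_term = 0.01`, snake
parameters `alpha = 0.20` (elasticity), `beta = 0.20` (rigidity),
`gamma = 1.00` (step), `kappa = 0.1` (external force scale) and at most
5000 iterations.  These weights follow the convention of 8-bit
active-contour implementations, where the line term multiplies gray
*levels* and the edge term squared gray-level gradients; `edge_map()`
therefore expresses the image on the 0–255 scale internally
(`intensity_scale`, configurable).  On a [0, 1] scale the same numbers
would let the line term dominate and the contour would drift toward
bright interiors instead of edges.

`gvf_field()` minimizes
`∬ μ(|∇u|² + |∇v|²) + |∇f|² |(u,v) − ∇f|²`
by explicit diffusion with the stable step `dt = 1/(4μ + max |∇f|²)`
(larger steps are rejected by name of the bound).  As in the original
formulation the edge map is first normalized to unit peak, so `μ`
(default 0.2, 200 iterations) is defined relative to a [0, 1] edge map.
The iteration provably decreases the discrete functional — asserted
against brute-force energy evaluation — and its fixed point matches a
direct sparse solve of the Euler–Lagrange system on toy edge maps to
within 2 %.

`evolve_snake()` uses the standard semi-implicit update
`v⁺ = (I + γA)⁻¹ (v + γκ F(v))` with the circulant pentadiagonal
internal matrix `A` built from `alpha`/`beta`.  The GVF force is
normalized to unit vectors (the usual practice), so `kappa` is a step in
pixels regardless of image contrast.  Two numerical details matter:

* vertices are resampled to uniform arc length every 50 iterations
  (default 200 vertices ≈ 1 px spacing on a breast-scale contour);
* at equilibrium vertices still oscillate across the edge ridge with
  amplitude ~`kappa` and slide tangentially along the curve, so the early
  stop measures the *curve-to-curve* drift (mean distance of current
  vertices to the previous window's polyline, per iteration) against
  `converge_tol = 0.01` px rather than raw vertex displacement.  On
  phantoms the snake typically stops after a few hundred of the allowed
  5000 iterations with an identical contour.

A contour collapsing below 5 px² raises an error (bad initialization)
instead of returning an empty mask.

## Feature definitions and choices

* **Shape**: area `A` (pixel count), perimeter `P`, roundness
  `R = 4πA/P²` (exactly 1 for a perfect circle), compactness `C = A/P²`.
  The dimensionless `A/P²` form is used for `C`; the dimensional `A/P`
  variant exists as an off-by-default option.  `P` is measured on the
  traced pixel-centre boundary polygon, Douglas–Peucker simplified at
  1 px tolerance and corrected by `+π` for the half-pixel outward offset
  (exact for convex outlines).  This estimator keeps polygonal shapes
  honest (a digitized 20 × 5 rectangle yields `R` within 5 % of the
  analytic 0.503) while digitized circles converge to `R → 1` with
  growing radius — smooth-curve chain estimators fail the former, crack
  boundary length the latter.
* **First-order** (per channel, in-mask): mean, sample median (the
  grouped-data median formula degenerates to it on ungrouped pixel
  data), population variance, standard deviation, and Shannon entropy in
  bits from the 256-bin histogram with `0·log 0 := 0`.
* **Second-order**: contrast, correlation, energy and local homogeneity
  of the symmetrized, normalized co-occurrence matrix; 8 quantization
  levels at offset (1, 0) by default, with the four standard offsets
  available and averaged on request.  Correlation is defined as 0 when a
  marginal deviation vanishes.
* **Relation (asymmetry)**: for every left/right base pair,
  `ED = √((V_r − V_l)²)`, `BD = √(|V_r·V_l|)`, `D = |V_r − V_l|`.  For
  scalar features ED and D coincide algebraically; both are emitted to
  preserve the fixed 3-distances-per-pair layout (93 = 3 × 31 values).
  The absolute value inside BD keeps it real for sign-indefinite
  features such as correlation.

## The phantom generator

`phantom_spec()` / `render_phantom()` build a scalar temperature field on
[0, 1] — cool ambient surround (0.05), warm torso block (0.26), two
smooth-edged breast ellipses elevated to 0.44, optionally a Gaussian hot
spot (+0.30 at its centre, radius 5 % of image width) in one breast —
add seeded Gaussian noise (sd 0.01 by default) and map it through an
invertible piecewise-linear blue→green→red palette.  Ground-truth masks
are rasterized exactly from the spec ellipses, and the inverse palette
lets tests reason about temperature directly from rendered colours.

The geometry (breasts centred at 0.30/0.70 of the width with semi-axes
0.13 W × 0.25 H, protruding below a torso spanning 0.10–0.90 W) is
chosen so that the binarized silhouette margins carry the breast arcs
with clearly separated junction corners, and the temperature levels so
that grayscale conversion leaves usable edge contrast at *both* the
breast/ambient and breast/chest-wall boundaries with a clean 0.25
threshold in between.  `make_dataset()` jitters centres (±2 px), axes
(±8 %), breast elevation (±0.02) and hot-spot elevation (±0.04) from a
single master seed.

What the phantoms deliberately do **not** model: bioheat physics,
vascular patterns, camera noise spectra, pose variation, or the
inter-subject anatomical variability of clinical thermograms.  Passing
the phantom suites therefore demonstrates the internal correctness and
robustness of the algorithms under controlled asymmetry cues — not
clinical performance.

## Classifiers

The three feature-based learners are thin wrappers over standard
implementations (`randomForest`, `nnet`, `e1071::naiveBayes` — the
"Bayes network" is realized as naive Bayes, the structure its usual
desk-scale reading).  The MLP standardizes features with train-fold
statistics.

The convolutional classifier is a deliberately small, fully
config-driven stack written in plain R: one valid convolution layer
(16 filters of 3 × 3 by default, leaky ReLU), one subsampling pooling
layer (global max pooling by default; block average/max selectable), an
optional hidden fully-connected layer, and a sigmoid output, trained
full-batch with Adam (learning rate 0.01, 150 epochs) on the binary
cross-entropy.  Inputs are the segmented images (background zeroed)
resized square; 277 px is the default side, with any smaller side
selectable — the tests use 32 px.  The defaults were chosen for
optimization robustness on very small training sets: global max pooling
makes a localized hot-spot cue position-invariant and learnable from a
handful of examples, and the leaky activation keeps gradients alive for
filters that start out ignoring the relevant channel.  No claim is made
of reproducing any particular trained network.

Evaluation is stratified, seeded 2-fold cross-validation: each half
trains once and tests once, so every sample is tested exactly once;
per-fold and pooled confusion matrices, the indicator set and the
Mann–Whitney rank AUC (midranks for ties) are reported.  Indicators with
zero denominators are `NA`, never silently 0.  The positive class is
"normal" throughout.

## Problem sizes and determinism

The test and acceptance suites run on 160 × 120 phantoms, 20-phantom
segmentation batches and 40-phantom classification datasets, with the
CNN at a 32-px input side — sizes at which the full pipeline (two GVF
fields and snakes per image) takes well under a second per phantom in
plain R while leaving every algorithmic property intact.  All
randomness — phantom draws, fold splits, forest/MLP/CNN training — flows
from explicit seeds through isolated RNG scopes, and the segmentation
path is fully deterministic: identical inputs give bit-identical masks.

## Known limitations

* The curvature initialization assumes a frontal view with exactly one
  breast per image half whose lower arc reaches the silhouette; lateral
  or oblique views and scenes with more than two candidate regions are
  rejected, not guessed.
* The perimeter offset correction `+π` is exact only for convex
  outlines; strongly concave regions would bias `R` and `C` slightly.
* The "grayscale" of a pseudo-colour thermogram is not monotone in
  temperature under a rainbow palette; the pipeline needs usable gray
  contrast at the breast boundary, which holds for the palette and
  levels used here but is not guaranteed for arbitrary colour maps.
* BD's absolute value makes it a similarity-flavoured magnitude rather
  than a proper Bhattacharyya distance between distributions; it is kept
  because the per-pair scalar layout requires a real-valued quantity.
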