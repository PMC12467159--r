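---
title: "Texture descriptors, feature reduction and evaluation in octatex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture descriptors, feature reduction and evaluation in octatex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octatex)
```

## The problem and the model

En-face OCTA slabs of the four ocular vascular layers are greyscale
images whose diagnostic content is textural: healthy layers show
organised capillary meshes and vessel filaments, whereas AMD introduces
neovascular tangles, flow voids and atrophic dropout. `octatex`
classifies eyes into binary condition tasks from dense local texture
statistics, deliberately avoiding lesion segmentation and its manual
annotation burden.

Each image is coded pixel-by-pixel by one of three descriptors and
summarised as a histogram; histograms of the layers in a combination
are concatenated per eye; eyes are classified with KNN or SVM, either
on the whole histogram features or after standardization + PCA
("reduced" mode). All reported performance comes from stratified
k-fold cross-validation.

## Descriptor definitions and conventions

**Circular sampling.** The neighbourhood of a centre `(x_c, y_c)` is
`p` points at offsets `(-r sin(2πn/p), r cos(2πn/p))`, `n = 0..p-1`,
with the first sample exactly one radius to the right of the centre and
a fixed angular direction. Off-grid samples use exact 4-point bilinear
interpolation; offsets within 1e-9 of an integer are snapped so that
axis-aligned samples bypass interpolation.

**Sign threshold and ties.** The bit for neighbour `n` is
`s(g_n - g_c)` with `s(x) = 1` iff `x >= 0`: ties give bit 1. Because
an interpolated value that is mathematically equal to the centre can
land a few ulps below it, the comparison uses a 1e-9 tolerance
(`g_n - g_c >= -1e-9`). With integer 8-bit data this changes nothing
else.

**riu2 mapping.** The uniformity measure counts circular 0/1
transitions, including the term that closes the circle between the
last and first bit. Patterns with at most two transitions are labelled
by bit count (0..p), all others share label `p+1`, so exactly `p+2`
labels exist and `p(p-1)+2` of the `2^p` codes are uniform. Both the
transition count and the `ROR` minimal-rotation canonicalisation are
verified against exhaustive enumeration in the test suite. One
printed-prose transition count for the pattern `01010011` differs from
the circular measure (5 vs 6); the formula, under which the pattern is
non-uniform either way, is taken as normative.

**Borders.** Dense coding excludes a margin of `ceiling(r)` pixels
(patch-fitting anchors for BRIEF): padding would fabricate texture the
image does not contain. Histograms are therefore over
`(H - 2 ceiling(r)) × (W - 2 ceiling(r))` codes.

**Histogram normalization.** Histograms are stored as counts and
normalized to relative frequencies on demand; pipelines default to
normalized so that layers with different valid areas remain comparable
after concatenation. Whether the original methodology normalized is
not stated; normalization is the only choice that makes concatenated
bins commensurable and is the package default.

**BRIEF.** One random sampling pattern of `n` pairs inside an `S×S`
patch is drawn per run (seeded) and shared by every image: a per-image
pattern would make histogram bins incommensurable across images. Pairs
with coincident endpoints are redrawn. The patch is anchored with the
coded pixel at zero-based offset `floor((S-1)/2)`. The binary-test
threshold is `3σ` where `σ` is the standard deviation of
`image - gaussian_blur(image)`; the blur uses `σ_blur = 1` pixel with
the kernel truncated at `4σ_blur` and replicate edges — small enough
to leave vessels in the residual mostly untouched while capturing
pixel-scale noise. These parameters are recorded in the configuration
so runs are exactly reproducible. On vascular texture the residual
also contains fine vessel edges, so the estimate upper-bounds the pure
speckle contribution; the test suite checks that the threshold grows
with the injected speckle level rather than asserting a fixed value.

## Invariance properties: what holds exactly

Adding a constant to every grey level leaves LBP, riu2 and BRIEF code
maps bit-identical (all decisions are differences; the blur residual is
also offset-invariant). Affine maps `a·x + b`, `a > 0`, commute with
bilinear interpolation and likewise leave LBP/riu2 maps identical. A
*nonlinear* strictly increasing transform is exactly invariant only
where every sample lies on a grid pixel (e.g. `p = 4, r = 1`);
interpolated samples can cross the centre value under such transforms.
This limitation is inherent to interpolated circular sampling and is
tested accordingly. Rotating an image by 90° permutes the circular
samples by `p/4` positions when `4 | p`, so riu2 histograms of the
interior are exactly preserved while generic LBP histograms need not
be.

## Standardization and PCA

Columns are centred and scaled with the *population* standard
deviation (divisor `N`), while the covariance matrix uses divisor
`N−1`, both as printed in the source methodology; the inconsistency
rescales every eigenvalue by the same factor and cannot change the
selected dimension `K`. Zero-variance columns are mapped to zeros (not
dropped) so `F` is stable across folds. `K` is the smallest integer
whose cumulative explained-variance percentage reaches the retention
threshold (default 95). For `F > N` the eigenpairs come from the SVD
of the standardized matrix (`λ_j = s_j²/(N−1)`), which is exact and
avoids forming an `F×F` matrix when `F = 2^16`. Eigenvector signs are
fixed (largest-magnitude entry positive) for reproducibility.

Whether the original study fitted PCA once on all data or per fold is
not stated. Fitting on all data leaks test information, so `octatex`
fits the standardizer and PCA inside each training fold and projects
the held-out fold with those fitted transforms; the whole-dataset
variant can be reproduced by reducing features before calling the
evaluator.

## Classifiers and evaluation

No SVM implementation exists in the supported dependency set, so the
C-SVM is implemented in the package as a deterministic Platt-style SMO
over the dual, with linear `x·y`, RBF `exp(-γ‖x-y‖²)` and polynomial
`(γ x·y)^d` kernels (the parameterization of the software environment
the methodology was developed in). The partner-selection heuristic
falls back over all candidates in a fixed order, so training is
deterministic and terminates at KKT-tolerance 1e-3 (hard cap 200
sweeps). KNN uses three distances with documented deterministic
tie-breaks: equal distances at rank `k` resolve to the smallest
training index, and a 50/50 vote predicts the negative class.

AUC is the Mann–Whitney probability-of-correct-ranking with ties
counted ½, computed from continuous scores: the SVM's signed decision
value and the KNN's positive-vote fraction (how AUC was obtained from
KNN is not stated in the source; the vote fraction is the standard
choice). Stratified folds shuffle within class and deal fold sizes
that differ by at most one, rotating the "+1" folds across classes so
total fold sizes stay within one of each other.

Hyper-parameters are selected by the same cross-validation used for
reporting — replicating common (optimistic) practice. This inflates
the best grid point's expected AUC above its generalisation value,
which is visible in the null experiments below; nested CV was
deliberately not silently substituted because the contract is to
reproduce the reported procedure.

## The synthetic generator: what it emulates and what it does not

Class A ("healthy-like") images are random smooth spline curves
stroked at width 1–3 px and Gaussian-blurred — filamentous bright
vasculature on a dark background, with per-layer vessel counts chosen
to mimic the relative density of the four slabs. Class B ("CNV-like")
adds, at a controllable `lesion_density`, clusters of *granular*
bright texture and dark dropout patches. Granularity is a deliberate
design choice: flat bright discs produce riu2 histograms nearly
indistinguishable from the vessel background (measured during
development), whereas real neovascular tangles read as pixel-scale
intensity disorder, which is exactly what LBP-family descriptors
detect. Lesion coverage is an *area fraction* (18% blobs, 8% dropout
at density 1), so class separability does not depend on the rendered
resolution — tests render at 64–96 px instead of the native 320 px
purely for runtime. Speckle is signal-dependent additive noise with
standard deviation `speckle_sd · sqrt(I/255)` grey levels, clipped to
[0, 255]; `speckle_sd = 0` gives noiseless images, density 0 makes the
two classes identically distributed (a true null).

The generator does **not** model physical OCTA decorrelation
statistics, projection artefacts, inter-device contrast differences,
or disease-specific lesion morphology. A green end-to-end test
therefore establishes that the pipeline detects constructed
micro-texture differences at the stated sample sizes — not clinical
performance on hospital data, whose headline results are explicitly
out of scope.

## Numerical choices and degenerate inputs

* Sign-threshold tolerance 1e-9 (see above); offsets snapped at 1e-9.
* Constant images: riu2 maps are all `p` (every neighbour ties), BRIEF
  codes all 0 (strict `>` against a non-negative threshold), noise σ
  is exactly 0.
* Zero-variance feature columns standardize to zeros and are flagged.
* `pca_select_k` uses a 1e-9 slack on the threshold comparison so a
  cumulative PV of exactly 95 selects that component count.
* Grid-search ties on mean AUC break by smaller sd, then grid order.
* All randomness (sampling patterns, fold shuffles, the generator)
  derives from explicit seeds through a private RNG stream that leaves
  the caller's `.Random.seed` untouched; per-image seeds derive from
  the master seed and stay below 2^31.

## Known limitations

* The SMO solver targets the small-N regime of eye-level studies
  (hundreds of rows); it forms the full kernel matrix.
* Generic LBP with `p = 16` produces 65,536-bin histograms; memory is
  fine but most bins are empty at OCTA image sizes, and the reduced
  pipeline is the practical route there.
* TIFF input is not supported (no codec in the supported dependency
  set); PGM/CSV are native, PNG optional.
* Nonlinear monotone invariance is approximate off-grid, as discussed.
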