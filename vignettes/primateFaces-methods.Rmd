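---
title: "Methods: LBP face identification and social-proximity analysis"
author: "primateFaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LBP face identification and social-proximity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primateFaces)
```

# Overview

`primateFaces` implements an individual-identification pipeline for primate
faces built on masked, block-wise uniform local binary pattern (LBP)
histograms, together with the downstream social-proximity analysis that such
identifications enable: windowed sighting aggregation, association indices,
Mantel matrix correlation, and a group-membership permutation test for
preferred associations. A seeded synthetic-data generator stands in for
colony footage so that every stage is testable end to end.

This vignette records the models, the tunable parameters and the design
decisions in one place. Everything quantitative said here is computed by the
package's test suite or its acceptance script; nothing is quoted from
external data.

# The feature descriptor

A face crop is processed in five deterministic stages:

1. **Grayscale** — color input is collapsed with the standard luma weights
   0.299 R + 0.587 G + 0.114 B (intensities 0–255).
2. **Canonical resize** — bilinear interpolation to 100 × 100 px, the crop
   size used throughout.
3. **Corner mask** — a fixed binary mask excludes four right-isosceles
   corner triangles (default leg 30 px). Corners are where back-lighting
   contaminates face crops of this species; the face itself occupies a
   roughly elliptical central region. The mask *excludes pixels from
   histogram accumulation* but does not alter intensities, so it cannot
   create artificial LBP edges along its boundary. The exact corner size is
   a free parameter (`cornerLeg` in `featureConfig()`): published sources
   show such masks schematically without dimensions, and 30 px removes the
   corners while keeping the full face ellipse.
4. **LBP transform** — each interior pixel is compared with its 8
   neighbours. We implement the comparison as bit = 1 when the *centre* is
   strictly lighter than the neighbour (ties give 0), with the conventional
   texture-analysis direction (neighbour ≥ centre) available as
   `convention = "standard"`. The two conventions relabel codes
   one-for-one (bitwise complement), so they only permute histogram bins;
   the tests verify that complementing every code preserves uniformity.
   Neighbours are ordered clockwise from the top-left pixel and packed
   most-significant-bit first. No published convention fixes this ordering;
   any fixed choice is internally consistent. The 1-pixel border has no
   full neighbourhood and is excluded from all histograms.
5. **Block histograms** — the 100 × 100 code image is cut into a 5 × 5 grid
   of 20 × 20 px blocks (row-major). Each block contributes a 59-bin
   histogram over the uniform-pattern bins: the 58 codes whose circular
   8-bit pattern has at most two 0/1 transitions get one bin each, all
   remaining codes share a catch-all bin. Concatenation gives the
   25 × 59 = **1475-element feature vector**.

Per-block histograms are L1-normalised by default (each non-empty block
sums to 1). Raw counts depend on how many in-mask, non-border pixels a
block contains, which differs systematically between corner and centre
blocks; normalisation removes that nuisance scale and keeps the chi-square
distance and the discriminant classifiers numerically comparable across
blocks. Raw-count mode (`normalize = FALSE`) is retained, and the tests
check count conservation in that mode.

Because every bit in an LBP code is a pure intensity *comparison*, adding a
constant to all pixels leaves the feature vector unchanged; the suite
asserts this illumination-shift invariance exactly.

# Classifiers

Three closed-set classifiers operate on feature vectors, optionally in a
PCA-reduced space:

* **NN** — nearest neighbour under the chi-square histogram distance
  $\sum_i (x_i - y_i)^2 / (x_i + y_i)$ (bins with $x_i + y_i = 0$ are
  skipped), the customary distance for LBP histograms. Euclidean distance
  is available by configuration. PCA scores are signed coordinates, not
  histograms, so when PCA is enabled and no distance is named, NN uses
  Euclidean distance.
* **LDA** — Gaussian discriminant with one *shared diagonal* covariance
  matrix pooled across classes, uniform priors. Pooled per-feature
  variances are floored at 1e−9 so constant features cannot divide by
  zero. Uniform priors reflect the balanced training sets the experiment
  harness constructs; with 1475 features and modest sample sizes a full
  covariance would be singular, which is precisely why the diagonal
  restriction is used. LDA requires at least 2 samples per class.
* **SVM** — linear kernel, cost 1, one-vs-one. Fitting is delegated to
  libsvm (via e1071); at training time the pairwise linear hyperplanes
  (w, b) are extracted from the support vectors, so prediction is the
  package's own majority vote with a documented tie-break: ties in votes
  are broken by the summed signed decision values, then by label order.
  This also makes SVM models serialisable to plain JSON. Tests verify the
  extracted-hyperplane predictions against the library's own.

**PCA** retains the smallest number of components whose cumulative
explained-variance fraction exceeds 0.95. PCA is fitted on the training
vectors of each trained model (and refitted per fold in cross-validation),
never on test data — a global fit would leak information across the
evaluation boundary. On the synthetic datasets this keeps roughly
100–200 of 1475 dimensions.

Evaluation reports rank-1 accuracy (percent of test faces whose top
prediction is the true identity) with the full actual × predicted confusion
matrix and per-class percentages. Cross-validation uses stratified folds
(per-class fold sizes differ by at most one) under a caller-supplied seed.
The experiment harness `runAccuracyExperiment()` sweeps group size M and
training images per identity N with disjoint train/test images per repeat.
Timing is hardware-dependent and deliberately not asserted anywhere.

# Face validation geometry

A face-candidate crop (100 × 100) is accepted as *Good* only when three
sub-searches all fire:

* subject's right eye in the image-left upper quadrant [0, 50) × [0, 50),
* subject's left eye in the image-right upper quadrant [50, 100) × [0, 50),
* nose in the central column, default region x ∈ [30, 70), y ∈ [30, 100)
  (configurable; the region generously covers a 13 × 21 px nose template in
  the lower two thirds of the crop).

Landmarks are the centres of the top-scoring hits. The acceptance rule is
monotone: removing feature hits can only change Good to Bad, never the
reverse.

Candidate generation is a pluggable backend —
`function(image, region) -> data.frame(x, y, w, h, score)` — so externally
trained cascade detectors can be slotted in. The reference backend used by
all tests is a normalised cross-correlation (NCC) template matcher
(`templateBackend()`): FFT convolution produces the correlation surface,
local maxima above a threshold become hits after non-maximum suppression.
One numerical guard matters: on perfectly flat windows the FFT leaves a
tiny positive variance residue that would explode the correlation ratio,
so windows whose per-pixel intensity variance is below 0.25 score 0. The
default acceptance threshold for the eye and nose backends is 0.6: on
synthetic renders true features score ≥ 0.75 across nuisance conditions
while edge artefacts of occluding boxes stay near 0.5, so 0.6 separates
the two with margin on both sides. Training of cascade detectors is out of
scope; only the acceptance geometry and its evaluation are implemented.

**Alignment** (`alignFace()`) estimates the similarity transform taking the
detected landmarks to canonical positions — right eye (30, 35), left eye
(70, 35), nose (50, 65) — exactly from the two eyes, or by least squares
from all three, and resamples the crop bilinearly. Alignment is idempotent
to within interpolation tolerance.

**Detection evaluation** matches detections to ground-truth boxes greedily
by descending IoU (one-to-one, threshold 0.5 by default; the matching
criterion for hand-labelled ground truth is a package choice since none is
standard). Sensitivity is 100·TP/(TP+FN); the false-positive rate is
reported both per frame and as a percentage of frames. `rocSweep()`
recomputes the metrics over a score-threshold sweep, optionally discarding
candidates that fail face validation first — the tests show the validated
("combination") sweep dominating the face-only sweep in false positives at
matched sensitivity on synthetic frames. `harvestFaces()` processes a
timestamped frame stream at 2 frames per second (the first frame of each
half-second slot) and emits only validated crops.

# Social-proximity analysis

Sightings (time, identity) are aggregated into **fixed consecutive
windows** of 60 s; an identity is present in a window when it has at least
3 detections there. Fixed bins mirror the 1-minute scan-sampling cadence of
manual scoring; sliding windows would double-count co-presences.

The **association index** between A and B is the simple-ratio index:
windows containing both, divided by windows containing A or B or both. It
is the natural estimator when all individuals in a window are scored as
associated and detectability is high, as here; the half-weight variant is
available by configuration. Indices are symmetric, in [0, 1], diagonal NA.

**Mantel test** — the statistic is the Pearson correlation of the
off-diagonal upper triangles; the null permutes the identities of one
matrix (rows and columns jointly). The p-value is two-tailed with the
standard +1 correction, or exact by full enumeration for small matrices
(used by the tests at n = 4, where all 24 permutations are enumerated).

**Preferred associations** — the null model permutes *group memberships*:
each elementary move swaps one individual from one window with one from
another, chosen so neither is already present in the receiving window.
Every move therefore conserves each window's group size and each
individual's total sighting count exactly (asserted in tests). The chain
applies 1000 burn-in moves, then records an association matrix every 100
moves until `nPermutations` (default 10,000) null matrices exist. These
chain parameters follow common practice for this family of permutation
tests, which is usually run with parameter choices unreported; they are
configurable. A pair is *preferred* when its observed index is strictly
greater than the null value at rank ⌈n(1 − α/2)⌉ (with n = 10,000 and
α = 0.01, the 9950th sorted value) and *avoided* below rank ⌊nα/2⌋. The
strict-inequality rank rule is conservative under the heavy ties that
discrete indices produce, so the realised type-I rate sits at or below
α/2 per tail; the suite measures it on null streams.

**Degradation experiment** — `corruptIdentities()` reassigns a chosen
fraction of sightings to a uniformly chosen *different* identity (so
achieved accuracy is exactly 100·(1 − fraction)%), and
`degradationCurve()` rebuilds the association matrix per corruption level
and correlates it with the reference, averaging over repeats. On synthetic
streams the curve is flat at low corruption and declines steeply toward
zero as accuracy approaches chance — the robustness property that makes
imperfect automated identification usable for association analysis.

# The synthetic generator

The generator emulates the *statistical structure* of the real problem,
not its appearance:

* **Identity templates** share one schematic face layout (elliptical face
  region, dark eye blobs at (30, 35) and (70, 35), nose ridge at (50, 65),
  mouth line) and differ by a per-identity smooth random texture field —
  white noise on a 13 × 13 grid, bilinearly upsampled, scaled to an
  intensity SD of 25. The mid-frequency texture (~8 px features) is what
  block-wise LBP histograms respond to, mimicking the role of fur and skin
  texture. The amplitude (25) against per-render sensor noise (SD 4) was
  fixed once when the generator was written, so that same-identity renders
  are reliably closer in chi-square distance than cross-identity renders.
* **Nuisance conditions** reproduce the four challenge categories:
  in-plane rotation (default 15°, landmark truth transformed), a linear
  illumination gradient (±60 across the width), an occluding flat
  rectangle (20–40 px), and a smooth vertical warp of the lower face
  (amplitude 2.5 px) standing in for expressions. The warp is local to the
  mouth/nose region because expressions deform the lower face while eyes
  stay put — which is also why expression is the least damaging condition
  for the classifier, and the tests assert the difficulty ordering
  good ≥ expression ≥ obscured ≥ rotation.
* **Detection frames** (default 240 × 320) carry a smooth textured
  background, dark clutter blobs, and 0–4 non-overlapping planted faces at
  scales 50–80 px with recorded ground-truth boxes.
* **Sighting streams** draw per-window presence independently per identity
  (background probability 0.2) plus forced pairs made jointly present with
  a stated probability; every present identity emits at least the
  presence-threshold number of detections (3 + Poisson(2)), so the
  windowed rebuild reproduces the realised presence matrix exactly and the
  generator can return the true association matrix alongside the records.

What the generator does **not** emulate: out-of-plane pose, real fur and
skin appearance, lighting geometry, motion blur, inter-individual
similarity structure (template textures are independent), or detection
confidence correlated with image quality. Passing tests therefore
demonstrate that the algorithms are implemented correctly and behave as
the method predicts under controlled signal/noise — not that any
particular accuracy will be achieved on field footage.

# Numerical choices and degenerate inputs

* Resize/warp interpolation is bilinear; warps sample the inverse
  transform with border replication.
* LBP ties (equal centre and neighbour) give bit 0 in both conventions.
* PCA refuses all-identical training vectors; LDA refuses singleton
  classes; coincident eyes are a degenerate-landmark error; empty
  threshold lists, non-positive windows and undersized permutation counts
  are parameter errors.
* SVM vote ties: summed decision values, then label order.
* Swap chains that find no legal move (e.g., all windows contain the same
  set) return their input with a warning, making the null distribution
  degenerate and nothing significant — the correct inference.
* Model JSON is written with 17 significant digits, which round-trips IEEE
  doubles exactly; a reloaded model reproduces predictions bit for bit.

# Problem sizes used by the checks

The test suite runs everything at desk scale: recognition checks use 10
identities with 20 training / 10 test renders per identity (and 42 per
identity for the training-size sweep over N ∈ {4, 8, 16, 32}, 3 repeats);
detection checks use 6–20 frames; the permutation tests use 200–300
windows with 500–1000 null matrices in tests (the analysis default is
10,000); the degradation curve uses 300 windows, 6 corruption levels and 5
repeats. These sizes keep the full suite under a couple of minutes while
leaving every statistical assertion comfortably inside its sampling
tolerance.

# Known limitations

* Closed-set identification only: no rejection of unseen individuals.
* The reference detector is a template matcher for the synthetic face
  geometry; real footage requires an external detector behind the backend
  interface (cascade training is out of scope).
* In-plane alignment cannot correct out-of-plane pose, the dominant
  rotation mode in real footage.
* The simple-ratio index assumes all individuals present in a window are
  detected; systematic per-individual detectability differences would bias
  it.
* Timing benchmarks are reported by the CLI but never asserted: they are
  hardware-dependent.
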