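---
title: "Modeling the developmental alignment of symbolic and nonsymbolic number"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the developmental alignment of symbolic and nonsymbolic number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Children first discriminate quantities nonsymbolically — more dots, more
sounds, more touches — and only later map those quantities onto symbols
such as Arabic numerals. How that mapping is established matters: the
quality of the symbolic-nonsymbolic link predicts later mathematical
skill. `numalign` simulates this developmental trajectory in a compact
convolutional network modeled on the dorsal visual stream (V1 → V2 → V3 →
intraparietal sulcus, IPS) and asks when knowledge acquired on dot-array
comparison *generalizes* to numeral comparison, and what happens in the
network's IPS representation when it does.

The simulation contrasts two ways of teaching the mapping in the middle of
a three-stage curriculum:

1. **Stage 1 — nonsymbolic training.** The network learns to judge which
   of two dot arrays is more numerous.
2. **Stage 2 — mapping training**, under one of two conditions:
   *cross-format comparison* (judge a dot array against a numeral) or
   *cross-label mapping* (classify both formats into the shared labels
   1–9, interleaved minibatch-for-minibatch with dot comparison so the
   comparison skill is not immediately overwritten).
3. **Stage 3 — symbolic training.** The network learns numeral-vs-numeral
   comparison.

The central claim this package lets you reproduce at reduced scale: the
comparison-based mapping aligns the symbolic and nonsymbolic "number
lines" in the IPS layer and thereby produces generalization to purely
symbolic comparison *before* any symbolic comparison training, while
label-based mapping produces much weaker alignment and weaker
generalization; subsequent symbolic specialization partially erodes
nonsymbolic skill while preserving the ordinal structure of the mapping.

## Stimuli

### Dot arrays

Numerosity in dot displays is confounded with continuous magnitudes, so
the generator controls two of them explicitly, per image: the **total
foreground area** (summed dot area, realized as the foreground pixel
count) and the **convex hull area** of the dot configuration (centers
inflated by radii). A fixed set of (total area, hull area) parameter
pairs is shared across all numerosities 1–9, so neither cue predicts
number across the set. Placement is rejection sampling of non-overlapping
circle centers, followed by two deterministic corrections: the
configuration is rescaled about its centroid until the realized hull area
matches the target (binary search; the hull is computed on a polygonal
approximation of the discs), and the radii are rescaled until the
rasterized pixel count matches the target total area (binary search on
the integer-valued count). Defaults: realized area within 5% of target,
hull within 10%, at most 1000 placement attempts before an explicit
placement-failure error — never a silent partial image.

Unstated generation details were fixed once as follows. Total areas are
drawn log-uniformly over 1–10% of the canvas area and hull areas over
10–60%, spanning congruent and incongruent area-number relations; each
pair is then clamped per numerosity to the feasible region: a minimum dot
radius (about 1.3 px), a hull floor that leaves room to place `n` centers
at the enforced 2 px separation (1.5 × the hexagonal-packing area of the
separation discs), and a hull ceiling equal to 80% of the largest hull
`n` dots of that size can span inside the canvas. For a single dot the
only feasible hull equals the dot's own area, so the hull target is tied
to the total area. Dots in one image share one uniformly drawn RGB color
with luminance at least 0.3 against the black background; stimuli are
stored as luminance rasters (the network is luminance-driven), with the
color kept in the provenance record. Every image's provenance (parameters
plus seed) regenerates it bit-exactly, which the tests exploit.

### Numerals

The original protocol used MNIST digits upsampled from 28×28 to 224×224
by replicating each pixel into a constant 8×8 block. To keep the package
self-contained, the default symbolic generator instead renders fixed 5×7
glyph templates for 1–9 at 28×28 and applies a seeded random affine
perturbation (rotation ±15°, scale and shear ±10%, translation ±2 px)
emulating handwriting variability, then performs the same constant
block replication (factor 8 at full scale, 2 in the desk profile). Block
replication is exactly invertible by subsampling, which is tested.
`load_mnist_numerals()` reads real MNIST IDX files for fidelity runs but
is never required.

### Tasks

Comparison trials sample ordered number pairs (n, p), n ≠ p, uniformly
over the 72 ordered cells — ordered, not unordered, because the analyses
look for left/right asymmetries (a SNARC-like directional bias) that
unordered cells would average away. The correct response is the side with
the larger number; for cross-format trials the symbolic side is
randomized. Labeling trials pair each pooled image with its numerosity;
the merged set is the concatenation of the two single-format sets.
Training trials draw images only from training pools and test trials only
from test pools, so the splits never mix.

## Network

The trunk is four named convolutional stages (V1, V2, V3, IPS), each a
3×3 strided convolution with ReLU, optionally recurrent (a weight-shared
residual 3×3 convolution applied a configurable number of times, in the
spirit of recurrent vision models such as CORnet; the desk profile is
feedforward). The IPS feature is the spatially average-pooled IPS
activation, which makes the trunk fully convolutional: dot canvases
(64 px at desk scale) and numeral canvases (56 px) pass through the same
weights. Two linear decoders share the trunk: a 2-class comparison head
and a 9-class labeling head. Since no deep-learning framework is
available in this R stack, the convolutions and their backward passes are
implemented in the package (im2col + GEMM via RcppArmadillo) and verified
against finite differences in the test suite.

How two stimuli enter a comparison is not dictated by the task; the
default is **siamese** pairing — each side passes through the shared
trunk and the two IPS vectors are concatenated (left first) into the
2-class head. This preserves single-image IPS probing for the
representational analyses and retains side information through
concatenation order, which is what allows left/right asymmetries to
develop. A **composite** mode (both rasters abutted into one canvas) is
config-selectable.

Training is minibatch Adam (lr 1e-3, batch 32 by default) on softmax
cross-entropy. The comparison head is one persistent head reused by all
three comparison tasks; the labeling head exists only for the mapping
condition. Trunk weights are never frozen. All randomness — weight
initialization, batch order, trial sampling — derives from explicit
seeds, and two runs with identical seeds produce identical loss curves.

## Behavioral analyses

*Accuracy* is test accuracy over all trials; *(n, p) pair accuracy* is
accuracy over exactly the trials whose ordered pair is (n, p).
*Generalized* pairs are cells of an untrained task strictly above 95%
accuracy at a stage boundary; *forgotten* nonsymbolic pairs are cells
strictly above 95% at the end of mapping training and strictly below 55%
at the end of symbolic training. The strict readings of "above"/"below"
are deliberate and configurable; cells with no evaluated trials at desk
scale are reported as missing and excluded, never imputed.

## Representational analyses

For each number n and format f the mean IPS response over the test
labeling stimuli, x̄(n, f), gives 18 vectors. The **neural
representational similarity** between two of them is

> 1 − ‖x̄(n,f) − x̄(n′,f′)‖₂ / max ‖x̄(p,g) − x̄(p′,g′)‖₂,

a similarity in [0, 1] with unit diagonal and an exact zero at the
globally most distant pair. A numerical **distance effect** — closer
numbers represented more similarly — is quantified as the Spearman
correlation between |n − n′| and within-format similarity (negative =
distance effect).

The 18 means are embedded in 3 dimensions by metric MDS on their pairwise
Euclidean distances. Because no installed package provides metric stress
majorization, SMACOF is implemented here (~30 lines): deterministic
initialization from classical (Torgerson) scaling, Guttman transform
iterations, cap 3000, relative stress tolerance 1e-9, a warning if the
cap is hit. Classical scaling serves as the independent cross-check on
exactly embeddable configurations in the tests.

MDS is defined only up to orthonormal transforms, so the embedding is
rotated to put the "number line" first: the first axis is the direction
maximizing the Pearson correlation between projected coordinates and
numerosity, pooled over all 18 points, with sign fixed so the correlation
is nonnegative. The correlation-maximizing direction has the closed form
v ∝ S⁻¹ cov(X, n) (S the coordinate covariance); note this is the
maximizer of the *correlation*, not of the covariance — the two differ
whenever the embedding's covariance is anisotropic, and a
1000-random-direction brute-force test pins down that the implementation
optimizes the stated objective. The remaining rows complete an
orthonormal basis, so rotated pairwise distances equal unrotated ones.

The projection of point (n, f) on the rotated first axis is r(n, f), and
alignment between the formats' number lines is summarized by (1) the
Pearson correlation between r(n, s) and r(n, ns) across n = 1…9 — the
rotation is fit on all 18 points, the correlation uses the 9 pairs — and
(2) the normalized average distance (1/9) Σₙ |r(n,s) − r(n,ns)| /
|r(9,ns) − r(1,ns)|, with absolute values throughout since it is a
distance. Both metrics are invariant to global orthonormal transforms of
the mean responses, which is enforced by a property test.

## The desk profile: what a green test establishes

The full-scale protocol (224×224 canvas, 50 parameter pairs × 12 images,
4500/900 comparison trials per task, 20 epochs per stage) is available as
the `"paper"` profile but is far outside a CI budget. The test suite and
the acceptance script run the `"desk"` profile, chosen once: 64 px dot
canvas, 2× numeral replication (56 px), 10 parameter pairs × 12 images
(900/180 dot images), 120 numerals per digit, 2000/400 comparison trials
per task, a 16/32/32/64-channel trunk, 8 epochs per stage. A full desk
experiment (both conditions, three stages) takes roughly nine minutes on
one CPU.

At this scale the full-scale point values are not expected to reproduce
numerically; what is checked instead is the *pattern*: high nonsymbolic
accuracy after stage 1 with above-65% cross-format generalization;
preserved (>94%) nonsymbolic accuracy through cross-format mapping;
strictly higher stage-2 symbolic accuracy, higher alignment correlation
and lower normalized distance under cross-format than under cross-label
mapping; a negative nonsymbolic distance-effect score after stage 1; and
a drop in nonsymbolic accuracy from the stage-2 to the stage-3 boundary
in both conditions (forgetting). Replicated desk runs (seeds 1–3 in the
suite) land near the full-scale values anyway — e.g. stage-2 symbolic
accuracy around 0.85 vs 0.64 across conditions and alignment correlation
around 0.94 vs 0.66 — but only the orderings and bounds are asserted.

The synthetic stimuli emulate the *statistical structure* of the original
datasets (controlled area and hull, handwriting-like glyph variability,
matched set sizes), not their appearance: glyph distortions are affine
rather than truly handwritten, dot colors enter only through luminance,
and the desk canvas holds many fewer pixels per dot. A green suite
therefore establishes that the mechanism — alignment through
comparison-based mapping — emerges under the stated controls at reduced
scale, not that any particular full-scale accuracy is reproduced.

## Known limitations

- The trunk is a scaled-down analog of the dorsal stream, not a
  weight-level CORnet-S replica; claims are about mechanism, not about
  biological fidelity beyond layer naming.
- Single-seed full runs are the default (as in the original protocol);
  seed-to-seed variability at desk scale is visible mainly in the exact
  pair sets, less in the qualitative orderings.
- Pair-accuracy cells at desk scale average ~5–6 trials, so generalized /
  forgotten pair sets are coarse; empty cells are reported as missing.
- Reaction times, Weber-fraction fits, and comparisons to human
  neuroimaging are out of scope.
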