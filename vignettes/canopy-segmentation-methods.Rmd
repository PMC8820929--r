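---
title: "Methods: CFitK-means segmentation and GLCM trait analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CFitK-means segmentation and GLCM trait analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfitkmeans)
```

## The segmentation problem and the model

A chlorophyll-fluorescence capture of a potted wheat plant contains
three intensity strata: background at exactly 0, the pot in a narrow
low-intensity band, and the fluorescing canopy above both.  Only the
canopy carries photosynthetic signal, so every downstream trait depends
on removing the other two strata first.  Two facts make a single fixed
threshold unreliable: the canopy brightens over the capture timeline as
the plant grows, and the pot is more exposed in water-stressed plants.

CFitK-means treats elimination as a function of *time*.  The threshold
is a cubic in the image's index `x` in capture order,

$$T(x) = p_1 x^3 + p_2 x^2 + p_3 x + p_4,$$

with defaults $p_1 = 2.273\times10^{-8}$, $p_2 = -4.118\times10^{-5}$,
$p_3 = 0.01699$, $p_4 = 11.95$ (intensity units on the 8-bit scale).
These coefficients are taken as given; the package deliberately does not
re-fit them, since the hand-tuned threshold records they were estimated
from are not distributed with it.  Over `x` in roughly 0–1200 the cubic
stays inside the usable elimination band of 11–17; as a guard against
extrapolation the evaluated value is clamped into
`[clamp_lo, clamp_hi] = [11, 17]`.  The raw value remains available
(attribute `"raw"`) for auditing.

Pixels strictly below $T(x)$ are set to 0 — "remove below `T`" keeps
`T` itself, a convention fixed here once because the boundary pixel has
to land somewhere and the elimination band's top (17) is exactly the
pot's top.

The second stage is 1-D K-means with $K = 2$ on intensities divided by
255.  Initialization is deterministic: from the histogram of surviving
intensities (those strictly above the threshold), the set of *occupied
levels* gives one seed at its mean (inside the canopy's intensity mass)
and one at its minimum (the dimmest survivor).  Among the plausible
readings of "mean of the histogram above the cutoff", using the
occupied levels (rather than bin counts or the raw pixel mean) is the
one that places the seeds on the intensity axis where the clusters
live, and it keeps the seeds independent of region areas.  Lloyd
iteration runs to assignment convergence or 20 iterations, whichever
comes first; an empty cluster keeps its previous centroid rather than
aborting.  The brighter final cluster is the canopy, and pixels removed
by the threshold can never be canopy regardless of cluster geometry.
If the threshold removes everything, the segmenter returns an
all-background mask with a warning instead of failing, so unattended
time-series runs continue.

### Baselines

Three reference segmenters support the evaluation layer: a global
static threshold (default 17, the top of the elimination band — no
canonical value exists, so it is configurable); Otsu's method over the
256-bin histogram; and 4-centroid intensity K-means seeded at the
quartile midpoints of the observed range, with the lowest cluster as
background.  Otsu tie-breaking: when several thresholds maximize the
between-class variance (a plateau between well-separated modes), the
middle of the plateau is returned, so a two-valued image thresholds
strictly between its two values.

## IoU evaluation protocol

Masks are compared by intersection-over-union.  Two empty masks score 1
(perfect agreement on absence) with a warning; this case only arises in
degenerate fixtures but must be defined for the protocol to be total.
`evaluate_segmenters()` draws mutually exclusive random samples — one
seeded shuffle, partitioned into consecutive blocks of the requested
sizes (so the dataset must hold at least the sum of the sizes) — and
reports both the count of images above the acceptance cutoff (0.5) per
sample and the mean IoU as a percentage, per round and pooled, since
either aggregation is a defensible summary and they differ on
heterogeneous datasets.

## The GLCM trait panel

Texture is summarized by 23 scalar traits of the grey-level
cooccurrence matrix.  Choices, in order of consequence:

- **Grey levels `ng = 9`** (a 9×9 matrix), configurable.  Every trait
  formula sums over the matrix dimensions, so the matrix size is the
  operative quantity.
- **Quantization**: equal-width bins over 0–255,
  `level = floor(intensity/(256/ng)) + 1`, capped at `ng`; levels are
  1-based, which matters for traits that weight by `i` and `j`
  (autocorrelation, sum average, ...), so 1-basing is fixed rather than
  configurable.
- **Offset (0,1), symmetric**: a single horizontal displacement with
  reverse-offset accumulation.  Averaging over four directions is a
  common alternative; it is deliberately not the default because a
  single symmetric offset keeps the matrix interpretable and the
  default panel reproducible.
- **Masked computation**: the panel describes the *canopy*, so pairs
  are counted only where both pixels are in-mask; a whole-image mode is
  available by passing a `NULL` mask.
- **Epsilon** `2.2e-16` (machine epsilon) inside every logarithm, so
  empty cells contribute exactly nothing.

Four formulas circulate in print with typographical impossibilities;
each fix is a documented toggle in `glcm_config()`, defaults chosen to
be the mathematically coherent form where the printed one is impossible
and the printed form where it is merely unusual: sum-of-squares
variance uses $(i-\mu)^2$, not $(1-\mu)^2$; difference variance is
centred on $\mu_{x-y}$ (the printed sheet repeats $\mu_{x+y}$); sum
entropy carries its minus sign; the second information measure of
correlation follows the printed no-square-root form by default, with
the square-rooted variant (bounded in $[0,1]$) one toggle away.  The
panel keeps both inverse-difference homogeneity traits (`homop` and
`homom1`) even though they are the same formula, because the 23-column
schema is part of the contract.  The normalized inverse differences
(`indnc`, `idmnc`) divide by `ng` as printed.

Degenerate inputs are flagged, not fatal: a one-level region has zero
marginal variance, so the two correlation traits return `NaN` with a
`degenerate_correlation` attribute; `extract_feature_table()` drops
images whose canopy yields no valid pairs and records the reason.

## Trait statistics

- **Correlation categorization** lists a variable in a range category
  (A: −1–0.09, B: 0–0.49, C: 0.5–0.89, D: 0.9–1.0) when at least one of
  its off-diagonal correlations falls inside the range.  The ranges
  overlap and so does membership; the inferred membership rule is
  recorded as a flag in the output rather than silently applied.
- **KMO** from the inverse correlation matrix (anti-image partials);
  **Bartlett's sphericity** by the standard χ² approximation.  These
  are suitability screens only — no factor analysis is built on top of
  them, because on near-collinear trait panels factoring is exactly
  what they are expected to advise against.
- **Agglomerative clustering of the 23 traits**: variables are points,
  instances coordinates; each variable is z-scored first (uniform
  scale), with constant variables mapped to the zero point rather than
  `NaN`; distances are squared Euclidean.  Six linkage rules go through
  `stats::hclust` (between-groups = average, furthest = complete,
  nearest = single, centroid, median, Ward on squared distances —
  the convention under which those coefficients are defined); the
  seventh, within-groups average linkage (merge cost = mean pairwise
  distance inside the merged cluster), has no implementation in the
  installed stack and is computed by a direct $O(n^3)$ agglomerator,
  trivial at $n = 23$.  Schedules are reported SPSS-style (clusters
  labelled by lowest member index, first-appearance stages, next
  stage); memberships are canonicalized by first variable appearance so
  the seven columns of the linkage comparison are directly comparable.

## What the synthetic generator emulates — and what it does not

`canopy_scene()` reproduces the *statistical structure* the segmenter
relies on: exact-zero background; a pot band uniform over integer
intensities 11–17; a canopy of elliptical leaf blobs with
truncated-Gaussian intensities at ≥ 18 before noise.  Control canopies
brighten with day (mean $40 + 0.5\,d$), drought canopies are dimmer
(mean $35 + 0.3\,d$) with blob radii scaled by 0.7, exposing more pot —
values chosen once as a plausible 60-day vegetative trajectory on the
8-bit scale, with the two condition curves separated enough that
condition effects are visible at any day.  Gaussian noise (sd in
intensity units, default 0) is added inside the pot and canopy supports
only, keeping the background property exact, then clipped to [0, 255].

Because pot (≤ 17) and canopy (≥ 18) supports are disjoint before
noise, a threshold at 17 recovers the canopy exactly when `noise_sd =
0`: that is the exact-recovery fixture the tests use.  The default
frame is 347×260, the native 1388×1038 frame scaled down 4× so a
full-suite run takes seconds; the native frame is one argument away.

What the generator does *not* emulate: photosystem-II physics, leaf
venation and overlap texture, illumination gradients, specular pot
highlights, or capture noise with heavy tails.  Tests passing on these
scenes therefore validate the *algorithmic contracts* (threshold
arithmetic, clustering behaviour, formula correctness, protocol
determinism) — they do not certify field performance on real imagery.
`make_feature_table()` similarly plants a known three-block correlation
structure (block sizes 15/6/2 matching the three trait families) to
give the clustering layer a recoverable ground truth; real trait tables
are noisier and their block boundaries are an empirical question.

## Numerical choices and problem sizes

Polynomial evaluation is by Horner's rule; thresholding uses strict
`<`; K-means ties in assignment go to the first (lower) centroid;
probability matrices are validated to sum to 1 within 1e−9; feature
equality against the naive-oracle implementation is asserted at 1e−10.
The test suite runs the segmenter suites at 96×72 and the ranking
comparison at the default 347×260 over 100 scenes, the planted-recovery
clustering at 200 instances, and the sampling-convergence checks at 500
rows — sizes at which every stochastic check is stable across seeds
while the whole suite stays fast.

## Limitations

- The cubic's coefficients are inherited constants; on a different
  camera, species or capture cadence they must be re-fitted, and the
  package only provides the clamp as a safety net.
- The single-offset GLCM is orientation-sensitive by design; rotating
  the camera changes the panel.
- Within-groups linkage recomputes merge costs naively; fine for 23
  variables, wrong tool for thousands.
- The evaluation protocol's "mutually exclusive samples" reading
  requires a dataset at least as large as the sum of the sample sizes;
  smaller datasets need a reduced size vector.
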