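---
title: "Methods: bar-image encoding, augmentation and transfer learning for tabular clinical data"
author: "tab2img"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bar-image encoding, augmentation and transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tab2img)
```

## The problem and the model

Small clinical tabular datasets — here a prostate-screening panel of PSA,
age and seven IPSS-style symptom frequencies scored 0–5 — are a poor fit for
convolutional networks: they have no spatial structure, and with fewer than a
hundred records there is little room for data-hungry models. `tab2img`
implements a representation that manufactures that structure. Each record
$x \in \mathbb{R}^m$ is min-max normalized to $v \in [0,1]^m$ and rendered as
an image of $m$ coloured vertical bars. The image of width $w$ is divided
into $m$ equal slots of width $b = w/m$; bar $i$ is left-anchored in slot
$i$, spans the full image height, and has width $v_i b$, so a feature at its
maximum fills its slot and an absent feature leaves its slot empty. Every
feature has a fixed, distinct colour, which makes per-feature pixel mass
exactly recoverable and gives the round-trip decoder used throughout the
tests.

Two things make this representation useful rather than decorative. First,
*image* augmentation becomes available for tabular data: elastic distortion
and morphological dilation/erosion perturb bar edges and widths — semantically,
small perturbations of the underlying feature values — without the
distributional guesswork of tabular oversampling. Second, the images can be
fed to a pretrained convolutional backbone under transfer learning, so the
trainable surface stays tiny.

## Normalization

`fitNormalizer()` learns per-feature min/max on training data only;
`applyNormalizer()` scales into $[0,1]$ and clips values outside the fitted
range (a test-time record can exceed the training range; clipping keeps the
encoder contract valid). Constant features normalize to 0 with a warning
rather than an error so that degenerate synthetic inputs do not halt a
pipeline. Whether min-max bounds should be refitted inside each
cross-validation fold is a genuinely open design point: refitting is
leakage-safe but makes the encoding fold-dependent; fixed declared bounds are
stable across refits but use information outside the data. Both are
supported; the default refits per fold, and `useDeclaredBounds = TRUE` pins
ordinal features to their declared 0–5 domain.

## Encoding geometry

Slot boundaries are `round(i * w / m)` with half rounded away from zero —
stated explicitly so rasters are bit-reproducible; slot widths differ by at
most one pixel and sum to `w`. Bar widths use the same rounding, and a value
small enough to round to zero width leaves a genuinely empty slot (no 1-pixel
floor): absence is information. Bars are left-anchored and full-height; the
source material does not specify anchoring or margins, and left-anchoring
makes decoding trivial while being visually equivalent. The palette is evenly
spaced hues at fixed saturation/value assigned in schema order —
deterministic and maximally distinct — on a white background. Images are
written as PNG only: a lossy format would break the exact-colour contracts.
The default raster is 640 × 480 (the size used for the prostate cohort
experiments); all geometry scales with `encodingConfig()`.

## Augmentation

`augmentImage()` applies elastic distortion, then random morphology:

* **Elastic distortion** draws per-axis uniform $[-1,1]$ noise fields,
  smooths them with a Gaussian of standard deviation $\sigma$ (pixels),
  scales by $\alpha$ (pixels), and resamples with bilinear interpolation and
  reflected borders. $\alpha = 0$ is the identity, exactly. A low $\sigma$
  gives localized ripples, a high $\sigma$ smooth waves.
* **Random morphology** applies bar dilation with probability $P_d$ and bar
  erosion with probability $P_e$, in a uniformly random order, each with an
  independently sampled rectangular structuring element (height ≤ 2,
  width ≤ 5 by default — wider than tall because bars vary horizontally).
  Depending on the draws this realizes dilation, erosion, closing or opening.
  On a white background, bar dilation is a grayscale minimum filter and never
  decreases the non-background pixel count; bar erosion is the maximum filter
  and never increases it. These monotonicity contracts are what the tests
  pin down, so the implementation convention is verifiable.

Defaults are $\alpha \in [40, 60]$, $\sigma \in [3, 5]$,
$P_d, P_e \in [0.7, 0.8]$, structuring element at most 2 × 5 — the parameter
ranges used with 640 × 480 rasters. When rendering smaller images the
package's tests scale $\alpha$ and $\sigma$ by the same factor as the width
(e.g. $\alpha \in [10,15]$, $\sigma \in [0.75,1.25]$ at 160 × 120), which
keeps the distortion geometrically equivalent.

`augmentTrainingSet()` returns the originals plus `k` augmentations per
image ($n(k+1)$ images; `k = 1` doubles the training set, `k = 9` enlarges
it tenfold, i.e. 83 training images become 830 in a leave-one-out fold of an
84-record cohort). Per-image seeds are derived from the master seed and the
image/replicate indices with a deterministic hash, so folds are independently
reproducible and nothing depends on iteration order.

Design choices worth stating: the structuring-element bound "(2, 5) or
smaller" is read as a rectangle with height ≤ 2 and width ≤ 5, sampled
uniformly per operator; the order elastic-then-morphology is fixed; the
morphology draw order (operator order, both gates, both element sizes) is
always consumed even when an operator does not fire, so the random stream is
identical across branches. The rectangular grayscale min/max filters are
implemented in compiled code in the package because the available image
stack only provides binary morphology.

## Transfer learning

The classifier is a frozen convolutional backbone plus a small trainable
head. Images are resized to the backbone's expected input and
channel-normalized with the backbone's statistics — the standard transfer
choice. The head is batch normalization over the pooled features, dropout
(default 0.5), zero, one or two hidden ReLU layers (default zero: a single
linear map), and a sigmoid output; training is Adam on the binary log-loss
for 20 epochs, learning rate 0.001, weight decay 0.01, batch size 16. The
backbone is bit-identical before and after training — a tested invariant, not
an intention.

The bundled `"tiny"` backbone is a deliberately small, randomly-initialized,
frozen extractor: one layer of eight He-scaled 3 × 3 filters, ReLU, and
average pooling on a 2 × 10 grid (wide because bar width, not height, carries
information), giving 160 features from a 30 × 40 input. Random convolutional
features followed by a trained linear readout are a classical baseline and
are sufficient for bar images, whose information is low-frequency occupancy.
It exists so that every test and script runs with no download and no GPU;
results with it say nothing about what a large pretrained backbone would
achieve on real data. Checkpoints are saved with R's standard serialization.

## Evaluation protocol

`runLoocv()` runs exactly $n$ folds. Inside each fold the normalizer is
refitted, training records are re-encoded, and the training images are
freshly augmented with a fold-specific derived seed; the held-out record is
encoded but never augmented, so no augmented copy of it can reach the
training set — the per-fold bookkeeping in the report makes this auditable.
Pooled held-out probabilities (not per-fold averages, which are degenerate
with one test sample per fold) feed the metric suite: confusion counts at a
0.5 threshold (ties toward the positive class — a screening context favours
sensitivity), precision/recall/F1 with the zero-denominator convention
"return 0 with a warning", ROC by threshold sweep with trapezoidal AUC
(equal to the Mann–Whitney statistic with ties counted one half), the Brier
score, and equal-width calibration bins (default 10; empty bins omitted).

`stackLoocv()` nests a second level inside each fold: level-1 members are
refitted from scratch (members are factories, not fitted models — required
for honest cross-validation), and a meta-classifier (default random forest)
is trained on member probabilities. The account of what the meta-classifier
trains on is ambiguous in the source description — in-sample level-1
predictions would leak optimism into the meta-features — so the default
builds *out-of-fold* meta-features from an inner stratified split
(`innerFolds`, default 5), and `metaInsample = TRUE` reproduces the literal
in-sample reading. Voting is provided by `hardVote()` (majority, ties to
positive) and `softVote()` (probability averaging with the same `>=`
threshold convention).

## Synthetic cohorts

The real 84-patient cohort is private, so `defaultProstateProfile()`
emulates its published structure: 45 negative / 39 positive; positives with
higher-location, narrower PSA (log-normal margins), IEBladder and Urgency
shifted toward high categories and broader in positives; age nearly
uninformative; and latent correlations ranked
corr(Urgency, IEBladder) = 0.55 > corr(PSA, Urgency) = 0.35 >
corr(IEBladder, UrinateAgain) = 0.25 > a 0.10 symptom baseline. Sampling is
a Gaussian copula: latent multivariate normals with that correlation, pushed
through class-conditional inverse CDFs (continuous) or cumulative-probability
partitions (ordinal). Only the *sign and ordering* of the correlations and
the qualitative marginal shapes are taken from the published description;
every numeric parameter is a modelling choice of this package, documented as
an assumption. Labels are block-assigned per class, matching a cohort of two
diagnosed groups.

`separabilityProfile(s)` interpolates all class-conditional margins between
their pooled midpoint ($s = 0$: identically distributed classes, a true
null) and the default profile ($s = 1$), extrapolating beyond it; continuous
locations move linearly, spreads interpolate only up to the profile's own
values (widening them further would undo the separation), and ordinal
probability vectors are exponentially tilted. $s = 3$ is used as the
"near-separable" end-to-end condition.

What passing tests on these cohorts shows — and what it does not: the
pipeline can extract a strong class signal through the image representation
(separable cohorts), and it manufactures none where none exists (null
cohorts, mean LOOCV AUC ≈ 0.5 over 20 seeds — a leakage guard). It does not
show that the package reproduces the real cohort's published performance;
those numbers depend on private data and pretrained backbones and are out of
scope by design.

## Problem sizes and numerical choices

The stochastic end-to-end checks run at reduced, fixed sizes chosen once:
160 × 120 rasters with proportionally scaled elastic parameters, the tiny
backbone at 30 × 40, one augmentation per training image, $n = 84$ for the
separable condition (5 seeds) and $n = 40$ for the null condition (20
seeds). Pixel rounding is half-away-from-zero everywhere; reflected borders
(without edge repetition) are used for field smoothing, resampling and
morphology; all randomness flows from explicit seeds through a single
multiplicative hash (`deriveSeed()`), so every fold, member and augmentation
replicate has an independent, reconstructible stream.

## Known limitations

* Single-row bar layouts allocate ever narrower slots as $m$ grows; the
  representation is designed for small feature counts.
* The tiny backbone is a test vehicle, not a substitute for a pretrained
  network; no claim about real-data accuracy follows from it.
* Missing values are rejected, not imputed.
* With weak level-1 members on small cohorts a random-forest meta-classifier
  can trail its best member; the stacking advantage observed in practice
  presumes strong members.
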