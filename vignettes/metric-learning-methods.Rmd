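---
title: "Few-shot polyp classification by deep metric learning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot polyp classification by deep metric learning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`polypembed` addresses classification of colorectal polyp images by
surface pattern when only a single image per polyp is available and the
number of polyps is a few dozen. Instead of learning a classifier
directly, it learns an embedding `f` from images into a low-dimensional
real vector space in which semantic similarity becomes geometric
proximity; classification is then carried out by simple distance rules
fitted on the embedded training images.

The encoder is trained as a triplet network: three weight-sharing copies
of `f` process an anchor `x`, a positive `x+` (same class, or an
augmented view of the anchor), and a negative `x-` (different class or a
different source image). The package implements this as a single model
applied three times, which is mathematically identical to weight-sharing
clones. The loss of one triplet is

$$\mathcal{L}(x, x^-, x^+) \;=\; \lVert f(x), f(x^+)\rVert_{\mathcal{D}}
\;+\; \max\bigl(0,\; m - \lVert f(x), f(x^-)\rVert_{\mathcal{D}}\bigr),$$

with margin `m = 20` and `D` the l2 metric by default (cosine distance is
available). Note the additive form: the positive-pair distance is always
penalized, while the negative term vanishes once the negative is pushed
beyond the margin — the margin therefore caps the achievable loss
reduction from separating negatives and prevents the degenerate remedy of
inflating the embedding indefinitely.

**Embeddings are deliberately not length-normalized.** An absolute margin
paired with the l2 metric is only meaningful if the embedding retains its
scale; on the unit sphere an l2 margin of 20 would be unsatisfiable.

## Encoder architecture

The contract is: convolutional feature-extraction backbone, global
average pooling of the final feature map, and one affine encoding layer
into a 64-dimensional latent space. The backbone here is a configurable
stack of 3x3-convolution / ReLU / 2x2-average-pooling blocks implemented
directly in vectorized R (im2col plus BLAS matrix products), with
backpropagation verified against finite differences in the test suite.

Residual-scale depth is intentionally not used: at the data scales this
package targets, a residual-depth network cannot be trained from random
initialization, and shipping externally pretrained weights is outside the
package's scope. A two-block backbone (8 and 16 channels) on 32 px inputs
is the working configuration used throughout the tests and the
reproduction script; wider and deeper stacks on 224 px inputs are the
configured production default. Average pooling (rather than max pooling)
keeps the network differentiable everywhere, which makes gradient
checking exact.

## Training

* **Optimizer** — Adam with learning rate 1e-3. The rate is larger than
  would be appropriate for fine-tuning a pretrained backbone because here
  the network trains from random initialization within a small epoch
  budget; it is exposed in `train_config()`.
* **Epochs** — one epoch is 100 freshly mined triplets (the conventional
  epoch size for fine-tuning on few-shot polyp data); at most 100 epochs
  by default.
* **Validation and early stopping** — 25% of the corpus is held back.
  Validation triplets are mined once, unaugmented (except in the
  self-supervised regime, where the augmented view *is* the task), and
  the monitored quantity is the validation triplet loss. Training stops
  after `patience` (default 10) epochs without strict improvement, and
  the returned model carries the parameters of the best validation epoch,
  not the last.
* **Mining** — uniform over valid triplets, with no hard-negative
  mining; anchor and positive must be distinct samples (a coincident pair
  contributes no gradient signal). In the multilabel regime the negative
  must be completely class-disjoint from the anchor's label-set. The
  number of pretraining triplets per epoch is not canonical; it shares
  the 100-triplet default and is configurable.
* **From-scratch scale** — randomly initialized embeddings start with
  pairwise distances far below the margin, so the hinge is active for
  essentially all negatives early in training and the embedding expands
  gradually. Metric consolidation (intra-class tightening relative to
  inter-class spread) is therefore measured over tens of epochs, not a
  handful.

## Augmentation

The augmentation set is flips along both image axes, photometric jitter,
additive gaussian noise, and specular-highlight grafting, composed in
that fixed order. Jitter semantics: brightness and saturation are
multiplicative factors around identity, contrast scales deviation from
the image mean, hue is a circular rotation of the chroma plane (YIQ I/Q
components). Degenerate parameters are skipped entirely, so the identity
spec is exactly the identity. Default ranges — factors in [0.7, 1.3], hue
within 5% of the hue circle — operationalize "heavy" jitter and are fully
config-exposed, as no canonical values exist.

Specular highlights are detected as bright (`channel max >= 0.95`),
unsaturated (`(max - min)/max <= 0.25`) pixels, optionally dilated by a
disc; the threshold contract stands in for published detector algorithms
and is parameterized so a stricter detector can be substituted. Grafting
hard-replaces pixels under the mask — a saturated sensor records neither
texture nor noise — so everything outside the returned composite mask is
bit-identical to the input.

## Keyframe condensation

Videos are decomposed into scenes by matching consecutive frames:
Harris-corner keypoints with BRIEF-style binary descriptors (the ORB
family), matched by Hamming distance with mutual-nearest-neighbour and
translation-consensus verification. The score is accepted matches over
the keypoint count of the poorer frame; a new scene starts when the
score falls below 0.15. Geometric verification matters: on small frames,
coincidental descriptor matches are common, but only genuine
correspondences agree on a common translation. Within each scene the
keyframe is the frame maximizing the variance of the Laplacian (ties go
to the earliest frame); no canonical sharpness criterion exists, and
variance-of-Laplacian is the standard focus measure. Frames below about
64 px yield too few keypoints for reliable matching — the module is
designed for 64 px and up.

## Classifier heads and diagnostics

The embedded training images are the latent-space population. Three heads
are provided: 1-nearest-neighbour (stores the population verbatim),
nearest class-centroid, and an RBF-kernel SVM (`e1071`, cost 1, kernel
width from the median heuristic `1/(2 median ||z_i - z_j||^2)`,
embeddings not standardized — their scale is meaningful relative to the
margin). "Smallest average distance" is ambiguous between
nearest-class-mean and smallest mean distance to class members; the
class-mean reading is the default and the other is available via
`params$rule = "mean_distance"`. All exact ties break deterministically:
lowest training-sample index (1-nn) or earliest class in the vocabulary
(centroid).

The variance diagnostic reports per-class intra-class variance (mean
squared l2 deviation from the class mean — total, not per-dimension,
since only ratios are reported) and the inter-class variance of class
means around their grand mean, normalized so inter = 1; a zero raw
inter-class variance is reported as an error, never silently.

## Evaluation harness

Splits are drawn at polyp level (one image per polyp is enforced
structurally by the generators, so train/test polyp-disjointness is a
structural property), with 75% for fitting. Balanced test sets take the
smallest per-class nominal test allocation for every class; the excess
returns to the training side. Metrics follow the standard one-vs-rest
counting formulas; macro averages are unweighted class means, which makes
accuracy equal macro recall exactly on balanced test sets (an identity
the tests exploit). Per-repeat F1 values are averaged as such — the mean
F1 is not the F1 of the mean precision and recall. Confidence intervals
over repeats default to the symmetric normal approximation
`mean ± 1.6449 sd` at the 90% level; a percentile form is available since
printed symmetric intervals do not disclose which convention produced
them. The 2-D projection for error analysis is an exact t-SNE (quadratic
cost is irrelevant at these sizes; deterministic under its seed), with
PCA as an alternative; projections are never used in metrics.

## Synthetic data: what it does and does not show

The generators emulate the *structure* of the clinical problem, not its
appearance:

* **Polyp sets** — one image per polyp; two classes sharing base color
  statistics and differing only in surface texture: dark/white spots on
  an otherwise homogeneous mucosa-like base versus bright warped
  tubular/branched ridges. `pattern_contrast` scales the discriminative
  texture: at 0 the classes are statistically identical and recovery
  accuracy sits at chance; separability is monotone in contrast.
  Sensor noise (sigma 0.05) is added before highlights, and mucosal
  texture is capped below the specular range (0.93) — only rendered
  highlights saturate, which is both physically motivated and what makes
  highlight masks exactly re-derivable.
* **Texture corpus** — per-class texture signatures with a configurable
  fraction of two-label blends, for the multilabel pretraining regime.
* **Videos** — a camera traversing a large textured world; within a scene
  frames differ by ±2 px jitter and per-frame gaussian blur, between
  scenes the window jumps a full frame width. A fine-grained detail layer
  guarantees the planted unblurred frame is strictly sharpest in its
  scene regardless of jitter.
* **Highlight banks** — saturated near-white blobs with a narrow soft
  rim.

Every generator is a pure function of its spec including the seed.

Passing tests on these fixtures demonstrate that the machinery is
correct — the loss implements its formula, mining respects its
invariants, splits are disjoint, the metric consolidates, detectors
recover planted structure. They do not demonstrate clinical performance:
the synthetic classes are far more separable than NICE classes in real
endoscopic imagery, where reported accuracies are much lower than the
near-perfect recovery seen here. One consequence, observed and accepted:
with 40 polyps per class at contrast 0.8 the SVM head classifies the
synthetic test sets perfectly even from a randomly initialized encoder,
so the fine-tuning-vs-none comparison can tie at 100% rather than
exhibit the improvement a harder (clinical) task shows.

## Numerical choices and degenerate inputs

* Distances at coincident points use a guarded subgradient
  (`d/max(||.||, 1e-12)`); the ReLU subgradient at 0 is 0.
* Bounding boxes are 0-based, half-open; resampling is bilinear both
  ways; pixels are RGB floats in [0, 1].
* Division-by-zero conventions: precision/recall/F1 with empty
  denominators are 0; zero inter-class variance is an error.
* Problem sizes in the shipped tests and reproduction script — 32 px
  images, two-block encoders, 20 evaluation splits, 10-20 epoch budgets —
  are the package's working desk scale; every size is a config value.

## Known limitations

* No GPU path and no residual backbones; training beyond a few conv
  blocks at 224 px is impractical in pure R.
* The keypoint matcher assumes translational scene motion; rotation or
  zoom would defeat the translation-consensus check.
* Multilabel mining enumerates validity per anchor, which is quadratic in
  corpus size; fine for pretraining corpora of thousands, not millions.
* Style-transfer augmentation and polyp *detection* (bounding boxes are
  consumed, never computed) are out of scope.
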