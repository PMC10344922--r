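---
title: "slideroi: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{slideroi: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slideroi)
```

# The detection model

A whole-slide image is a pyramid of magnification levels whose pixel
dimensions scale proportionally with magnification. ROI detection runs on
the fixed grid of non-overlapping 224 × 224 blocks at 10×, in three gated
stages applied in a fixed order:

1. **Empty/fat gate** (1× rendition of the block): reject as `EMPTY` when
   strictly more than 75 % of pixels have luminance strictly above gray
   level 200. Both inequalities are strict; a block at exactly the 75 %
   fraction, or whose pixels sit at exactly gray level 200, is kept. The
   source material speaks only of "intensity", so luminance here is the
   ITU-R BT.601 weighted RGB sum rounded to the nearest integer — a
   deterministic, standard choice.
2. **Artifact gate** (1× rendition): reject as `ARTIFACT` when the
   fraction of near-black pixels (luminance ≤ 30) exceeds 0.5. Real
   artifact taxonomies (folds, bubbles, tears) are out of scope; the gate
   is a registered evaluator and can be replaced by name.
3. **Quality gate** (the block at its own magnification): reject as
   `POOR_QUALITY` when the variance of the 4-neighbor Laplacian response
   falls below a threshold. The published workflow delegates this step to
   an external reference-less quality algorithm whose internals are
   deliberately *not* reimplemented here; variance-of-Laplacian is the
   pluggable default because it is zero on constant images, isotropic
   under 90° rotation, and monotonically decreasing under Gaussian blur.

Surviving `CANDIDATE` blocks — and only those — are scored by the
classifier; screened-out blocks never reach it. Final states are five:
`EMPTY`, `ARTIFACT`, `POOR_QUALITY`, `REPRESENTATIVE`,
`NON_REPRESENTATIVE`.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| block size | 224 | px | input size of the classification backbones |
| detection magnification | 10× | — | accuracy/speed compromise of the reference workflow |
| `bright_threshold` | 200 | gray level | published empty/fat rule |
| `bright_fraction` | 0.75 | fraction | published empty/fat rule |
| artifact dark level / fraction | 30 / 0.5 | gray level / fraction | separates saturated smudges (luminance ≈ 10) from nuclei-dense tissue (≈ 70) |
| `quality_threshold` | 150 | Laplacian variance | sharp synthetic tissue scores 230–6800, blurred (σ = 3 at 10×) and flat regions ≈ 10; 150 sits an order of magnitude from both sides |
| consensus `k_required` | 3 | annotators | "all three pathologists" positivity rule |
| consensus `min_overlap` | 0.5 | block-area fraction | partial-coverage handling is unspecified in the source; half the block area is the symmetric convention |
| HER2 positivity cut-off | 2.0 | ratio | ASCO/CAP ratio threshold, consistent with every bundled score/status pair |

The quality threshold was fixed once at design time from measured
statistics of the synthetic world (see below) and is not tuned by any
test.

# Consensus labeling and dataset assembly

A block is *positive* iff at least `k_required` (default all 3) annotators
cover at least `min_overlap` of its area; coverage is computed by
rasterizing the annotator's rectangles onto the block so overlapping
regions are not double-counted. This rule is monotone: adding a mark can
only turn a block positive, never negative.

The 60/20/20 split uses ceiling rounding on the evaluation partitions per
class: `|val| = |test| = ceil(0.2 N)`, `|train| = N − 2 ceil(0.2 N)`. This
rule is chosen because it reproduces the published 4616/1540/1540
partition of 7696 tiles per class exactly ("approximately 60 %"). When
slide identifiers are available the test partition is assembled from whole
held-out slides (a bounded greedy search over shuffled slide orders that
must meet the per-class quota exactly); when no such combination exists
the split falls back to a random assignment with a warning.

Stratified k-folds deal each class round-robin after a seeded shuffle, so
per-fold class counts are within one item of the global ratio.
Augmentation (mirror flips, right-angle rotations, central-crop zoom)
composes deterministically; the identity settings are exact identities.

# Head-architecture enumeration

Classification heads connect the 1000-wide backbone feature vector to the
2-wide output through strictly decreasing hidden layers drawn from the
halving pool (512, 256, 128, 64, 32, 16, 8, 4):

* **halving chains** — the 9 prefixes of the pool (depths 0–8);
* **skip-one variants** — every single-hidden-layer omission from each
  chain: 36 raw omissions of which 8 (each chain minus its last hidden
  layer) reproduce a shallower chain, leaving 28 new architectures;
* **contiguous-run variants** — omitting every run of 2–7 consecutive
  hidden layers from the deepest chain: 27 raw of which the 6 trailing
  runs reproduce halving chains, leaving 21.

Total: 9 + 28 + 21 = 58 distinct architectures. The published description
of the omission procedure is ambiguous ("skipping only one layer from
these 9 architectures" vs "from the bottom architecture"); the
deduplication reading implemented here is the only simple procedure we
found consistent with all three printed counts (9, 28, 58), and is
documented as an interpretation, not as authorial intent. A known
consequence: the worked example 1000-512-256-128-64-32-16-8-2 *is*
produced by skipping the 4-neuron layer, but it coincides with the depth-7
halving chain and therefore counts among the 9, not the 28.

The hyperparameter grid enumerates the full Cartesian product of four
epoch counts, three batch sizes, four optimizers, two loss functions,
three learning rates, and four dropout rates — 1152 configurations — in a
canonical row-major order. Top-candidate selection maximizes accuracy with
deterministic tie-breaking (higher AUC, then fewer head parameters, then
canonical position).

# The desk-scale classifier

No deep-learning framework is assumed: the dense head (ReLU hidden
layers, softmax output, inverted dropout on the topmost hidden layer),
the optimizers (SGD with momentum, Adam, AdamW, Adamax, RMSProp), and
backpropagation are implemented directly in R matrix algebra.
Cross-entropy and one-hot Kullback–Leibler divergence share a gradient and
are treated as the same loss.

Two backbones carry the tests:

* `tiny_cnn` — a frozen, seeded feature extractor: 32 × 32 luminance
  input, eight fixed 3 × 3 filters (zero-mean except one DC-preserving
  averaging filter, so global luminance stays linearly decodable), ReLU,
  2 × 2 mean pooling, and a fixed random projection to 1000 features.
* `tiny_vit` — a small transformer encoder: 16 patch tokens plus a class
  token, embedding dimension 16, two blocks of two-head self-attention
  and a frozen feed-forward sublayer, residual connections, and a frozen
  projection of the class token to 1000 features. Layer normalization is
  omitted — a documented desk-scale simplification. Only the
  query/key/value/output projections count as MHSA parameters.

Fine-tuning modes mirror the transfer-learning designs compared in the
reference workflow: `HEAD_ONLY` freezes the backbone (verified bit-level
in tests), `MHSA_ONLY` trains only the attention projections through
analytic backpropagation (verified against finite differences), and
`MHSA_PLUS_HEAD` trains both. The ImageNet-scale backbone names (VGG16
… DenseNet121, ViT-B/32) resolve to seeded random-feature stand-ins with
the genuine models' output widths; they are synthetic, flagged as such,
and exist so that head/backbone width mismatches and the MHSA-mode guard
can be exercised — no pretrained weights ship with the package. The
published "24 pairs of MHSA and FFN" figure is stored verbatim as backbone
metadata and not validated against any canonical ViT-B definition, which
has 12 encoder blocks; the conflict is unresolved in the source.

Metric definitions are the exact confusion-matrix identities; AUC is the
rank-based Mann–Whitney statistic with half credit for ties (the source is
silent on ties), tested against the brute-force pairwise-concordance
oracle. The decision threshold is 0.5 on the positive-class probability.

# The synthetic world

The generator emulates the *statistics the downstream rules consume*, not
histology:

* bright fat/empty strip: > 90 % of pixels above gray level 200;
* ordinary tissue: sparse dark nuclei-like ellipses (luminance ≈ 70) on a
  pink background (≈ 195), mean luminance between the two screening
  anchors;
* representative regions: dense ellipses, mean luminance < 150;
* artifact regions: saturated near-black smudges;
* blur regions: medium-density tissue low-pass filtered with a Gaussian
  (σ = 3 at 10×, scaled to the base magnification).

Planted regions occupy cells of the 10× block grid, so every
representative region covers exactly one full classification block, and
representative/artifact/empty regions are mutually exclusive by
construction. Lower levels are exact area-average downsamplings of the
base, which preserves mean luminance (tested to within 2 gray levels).
Annotator simulation marks each true region independently with probability
`agreement_prob` and adds Poisson-many spurious marks from unoccupied
tissue cells; signal-count tables are independent Poisson draws (the
source states no distribution; Poisson is the standard count model).

What the generator does **not** emulate — and hence what a green test does
not establish: stain physics and color variation, scanner noise, realistic
artifact morphology, spatially correlated annotator disagreement, nuclei
segmentation error, and the visual complexity that makes the real
classification problem hard. A perfect score on synthetic slides validates
the *plumbing* (gate order, coordinate maps, consensus rule, metric
arithmetic), not clinical accuracy; the published cohort-scale accuracies
(97.2 % at 10×, 100 % at 20×) require the original slides and
GPU-fine-tuned backbones and are deliberately out of scope.

# Numerical choices and degenerate inputs

* Coordinates are 0-based, half-open, (x = column, y = row), in pixels at
  the stated magnification; partial edge blocks are dropped, not padded.
* Size and coordinate rounding is round-half-up (`round(22.4) = 22` for
  the 1× rendition of a 10× block); the factor-2 10×→20×→10× round trip
  is exact.
* Resampling is area-averaging (exact block means for integer factors,
  overlap-weighted otherwise); it is the mean-luminance-preserving choice.
* The split's ceiling rule, kappa's marginal-product expected agreement,
  and MSE's 1/n normalization are fixed by the published numbers they
  must reproduce (4616/1540/1540; κ = −0.15; MSE 4.30 and 0.012).
* Degenerate inputs: a single-class evaluation set reports `NaN`
  sensitivity or specificity with a warning; two constant, equal raters
  get κ = 1 by convention (logged); a zero total CEP17 count, an empty
  signal table, an overcrowded region demand, and a singular affine
  transform are errors.
* Training aborts with a diagnostic as soon as the loss or the logits
  become non-finite. Note that softmax saturation with clamped
  cross-entropy means an oversized learning rate usually *saturates*
  rather than diverges; genuine non-finite losses come from non-finite
  inputs or parameter overflow.
* The published test–retest table prints two scores at or above 2.0 with
  status Neg, contradicting both the cut-off rule and the companion
  table; it is transcribed verbatim and excluded from status-consistency
  checks (the anomaly is symmetric, so κ = 1 is unaffected). Recomputing
  the test–retest MSE and the clinical-vs-method correlation from the
  printed scores gives 0.005 and ≈ 0.997 against published 0.004 and
  0.993; the tests assert directional bounds rather than those exact
  digits.

# Known limitations

* The classifier is desk-scale by design; no claim is made about
  ImageNet-transfer accuracy.
* Vendor WSI containers (SVS/MRXS/NDPI internals) are not parsed; the
  pyramid I/O is PNG-per-level with a JSON sidecar.
* Registration between H&E and CISH/FISH slides is consumed as a given
  affine transform, matching the workflow's use of an external
  registration application; it is never estimated from pixels.
* Only binary Pos/Neg HER2 status is modeled; the guideline's equivocal
  categories are out of scope.
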