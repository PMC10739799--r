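---
title: "Goblet-cell segmentation and morphometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goblet-cell segmentation and morphometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gobletseg)
```

## The problem

Conjunctival goblet cells (GCs) secrete the mucins that stabilise the tear
film; their loss accompanies dry-eye disease and other ocular-surface
conditions, so GC density and morphology are diagnostically informative.
Moxifloxacin-based fluorescence microscopy (MBFM) renders GCs as bright,
roundish objects of a few tens of square micrometres, densely distributed —
individually and in touching clusters — over an irregular background
shadowed by sub-surface blood vessels. Counting and measuring them by hand
does not scale to mosaic scans covering square centimetres, and plain
thresholding struggles with the spatially varying background.

`gobletseg` implements an automated analysis chain for such images: a
dual-channel attention U-Net (DCAU-Net) for pixel-level GC segmentation, a
conventional U-Net baseline, the training and evaluation protocol around
them, and the downstream morphometry (density in cells/mm², area in µm²,
eccentricity, mosaic density maps, longitudinal comparisons). Because
in-vivo MBFM data are not redistributable, the package ships a synthetic
scene generator with exact ground truth; every stage is exercised end to
end against it.

## The segmentation model

DCAU-Net is an encoder–decoder network. Each encoder stage is a
*dual-channel convolution* (DCC):

* **Semantic channel** — a multi-scale block: one 3×3 convolution block in
  parallel with two stacked 3×3 blocks (receptive fields 3×3 and 5×5),
  summed. Each block is convolution → batch normalisation → ReLU with an
  identity shortcut (1×1 projection where channel counts differ).
* **Texture channel** — two blocks with asymmetric kernels, k×1 followed by
  1×k (default k = 7), capturing a large receptive field for texture and
  cell boundaries at 2k·C·C′ weights instead of k²·C·C′.

The two channel outputs are fused element-wise, I′ = semantic + texture.
The fused map feeds 2×2 max-pooling down the encoder, and a *global channel
attention* (GCA) module on the skip connection:

* squeeze: the channel descriptor is the per-channel spatial mean,
  Iˢ(c) = (1/HW) Σᵢⱼ I′(c, i, j);
* a 1×1 convolution condenses I′ to a single-channel map Iᴬ;
* the refined map is σ(Iᴬ) × Iˢ — an outer (broadcast) product of a spatial
  sigmoid attention map with the channel descriptor — and multiplies I′ on
  its way to the decoder.

The decoder mirrors the encoder: bilinear 2× upsampling, a 3×3 block that
sets the stage width, concatenation with the GCA skip output, and two 3×3
blocks; a 1×1 convolution with a sigmoid yields a probability map of the
input size. Inputs must be divisible by 2^depth.

The baseline is the classic U-Net layout (two 3×3 blocks per stage, 2×2
channel-halving convolution after upsampling, no residuals) with the same
one-channel sigmoid head; at the classic widths (depth 4, base 64) it
carries ≈31 M trainable parameters and accepts exactly the same batches.

### Open architectural choices

Several architectural details are genuinely open choices; the package
fixes them as follows (all exposed through `modelConfig()`):

* the two semantic paths are **summed**, not concatenated, so the channel
  count stays fixed for the element-wise fusion the GCA requires;
* texture kernels are k×1 then 1×k with k = 7, stride 1, same padding —
  pooling alone performs the downsampling;
* channel widths 64/128/256/512 at depth 4 (scaled-down configurations are
  used throughout the tests);
* the GCA's refined map multiplies the fused map I′ (rather than the raw
  pre-fusion features);
* decoders use bilinear upsampling + convolution; skips are concatenated,
  the U-Net convention;
* He-normal initialisation; the sigmoid head's bias starts at −2, the
  standard rare-foreground initialisation, which starts predictions near
  the background base rate and removes the early training plateau.

## Training objective and protocol

DCAU-Net trains with the compound loss
`0.7 · dice + 0.3 · focal`, where soft dice is
`1 − (2Σpg + ε)/(Σp + Σg + ε)` over the flattened batch (ε = 10⁻⁶) and the
focal term is the mean of
`−α(1−p)^γ g log p − (1−α) p^γ (1−g) log(1−p)` with γ = 2, α = 0.25 (the
focal-loss paper's defaults; only the 0.7/0.3 weights are part of the
protocol). The U-Net baseline trains with plain binary cross-entropy under
the identical loop.

The optimiser is Adam at learning rate 10⁻⁴ for up to 100 epochs, halved
every 20 epochs (the decay factor 0.5 is the package's choice, config-exposed), with early stopping on a
validation-dice plateau (patience 10) and the best-validation parameters
retained. Case-grouped k-fold cross-validation (default k = 5) assigns
whole cases to folds — fold sizes differ by at most one, every tile
inherits its case's fold, and no case appears in both train and validation.
Sixteen cases at k = 5 give fold sizes 4, 3, 3, 3, 3.

Batch-normalisation running statistics use momentum 0.3: evaluation-mode
predictions rely on them, and in short scaled-down runs a slower estimate
lags the quickly-moving batch statistics enough to distort validation
scores mid-training.

## Preprocessing, augmentation, ground-truth bootstrap

Tiles are contrast-normalised with CLAHE before any cropping (full-tile application before cropping is the package default and
config-overridable). The implementation is the classic tile-interpolated
algorithm: per-tile histograms clipped at `clipLimit` (normalized; default
0.01) of the tile's pixels with the excess redistributed evenly, CDF
mappings, and bilinear interpolation between tile centres. Training-time
augmentation draws random 512×512 crops (identical offsets for image and
mask) and applies right-angle rotations and flips — right angles keep
binary masks exact; masks use nearest-neighbour semantics throughout. No
augmentation is applied at test time; `runPipeline()` enforces this by
construction (the predict/evaluate stages never call the augmenter).

Ground-truth production is bootstrapped in the package as in practice:
sectional adaptive thresholding (the image is divided into rectangular
sections, each thresholded on its own histogram — automated here with
per-section Otsu as a reproducible surrogate for the manual choice),
then rough predictions from a baseline U-Net trained on those initial
masks, then manual refinement, which is out of computational scope: masks
travel as editable 0/255 PNGs for external editors.

## Evaluation

Pixel-level confusion counts feed recall TP/(TP+FN), precision TP/(TP+FP),
false-positive rate 1 − TN/(TN+FP), IoU TP/(TP+FP+FN) and Dice
2TP/(2TP+FP+FN). The identity dice = 2·iou/(1+iou) holds for every
counts-derived report and is asserted in the tests. (A common misprint writes Dice as
2×TP/(TP+FP+FN), which can exceed one; the package implements the
standard form, the only one consistent with the IoU identity and with
Dice values observed in practice.) When predicted and reference masks are both empty the
overlap metrics are 1 by convention and flagged `degenerate`.

Precision–recall curves sweep 256 thresholds with p ≥ t foreground (so
threshold 0 gives recall 1), and AP is the trapezoidal area over recall
with the curve anchored at recall 0 at the strictest threshold's
precision — a perfect 0/1 prediction scores AP = 1, and uninformative
uniform noise scores AP ≈ the foreground fraction. Per-image metrics
averaged across tiles are the default report; pooled-pixel variants are
also provided, since either convention is common in practice.

## Morphometry

Segmented regions are 8-connected components of the binarized probability
map — touching cells, including diagonal contact, merge into one region,
which reproduces the known undercount of aggregated cells and makes the
estimated density a lower bound on truth whenever clustering is present.
A minimum-area filter (default 5 px²) suppresses single-pixel noise; 0
disables it. Areas scale exactly with the calibration:
area_µm² = area_px · (µm/px)². Eccentricity comes from the moment-matched
ellipse, e = √(1 − λ_minor/λ_major), with pixels treated as unit squares
(+1/12 per axis in the second central moments) — this removes most of the
small-axis discretization bias (a rasterized ellipse with semi-axes ≥ 5 px
matches the analytic √(1−(b/a)²) within 0.02) and assigns single-pixel
regions e = 0. Coordinates are 0-based, row-major; mosaic positions are
measured from the top-left in mm, and an 8×8 mosaic covering 20×20 mm² has
a 2.5 mm pitch.

## The synthetic scene generator

The generator emulates the statistical structure of MBFM goblet-cell
imagery so that every downstream stage can be tested against exact ground
truth: bright rotated-ellipse cells with a Gaussian-like radial profile
(area ~N(80, 20²) µm², inside the reported spread of in-vivo estimates;
eccentricity uniform on [0, 0.7]); Poisson cell counts around
`targetDensity × area` with the default 1500 cells/mm² in the middle of
the 1000–2400 range typical of conjunctival imaging; touching clusters with probability 0.3 per
cell (neighbours placed closer than the sum of semi-minor axes so
components merge under 8-connectivity while remaining distinct
generator-truth regions); a smooth background gradient; dark curvilinear
vessel shadows that only darken; small bright non-cell artifacts excluded
from the mask; additive Gaussian noise; 16-bit quantization. Isolated
cells are rejection-sampled to keep them from touching, so with
`clusterProb = 0` component counting recovers the placed cells exactly.
Each rendering phase (background, vessels, cells, artifacts, noise) draws
from its own seed-derived stream, so scenes are bit-reproducible and
changing one phase's parameters cannot perturb another's draws. The field
of view per tile is not fixed by the modality, so µm/px is a free
calibration parameter.

What the generator does **not** model: realistic optics (PSF, depth of
field, defocus), staining heterogeneity, motion artifacts, cell-shape
irregularity beyond ellipses, or spatially correlated noise. Passing the
synthetic benchmark therefore demonstrates that the implementation is
correct and trainable and that the morphometry is exact — not that the
shipped configuration reaches in-vivo performance; real deployments should
retrain on real annotated tiles.

## Problem sizes used in the tests

The suite runs on a single CPU, so the networks are exercised at reduced
scale while keeping every architectural element: shape/attention/gradient
checks on ≤64×64 inputs with 4–12 base channels; the one-batch overfit
check (combined loss < 0.05 within 200 Adam iterations at lr 0.03) on one
64×64 scene with a depth-2/base-8 model; and the documented training
benchmark — 24 training + 6 held-out scenes of 64×64 px at 1 µm/px and
~1800 cells/mm², DCAU-Net depth 2 / base 12, Adam 6·10⁻³ with step decay
every 12 epochs, 40 epochs — which reaches held-out Dice ≈ 0.89 in a few
minutes and must stay ≥ 0.85. The 512×512 I/O contract is checked at
depth 4 with 8 base channels. `scripts/acceptance.R` re-runs the benchmark
from scratch and reports the measured quantities.

## Numerical conventions

* probabilities are clamped to [10⁻⁷, 1−10⁻⁷] inside log-losses;
* binarization is strict (p > t); PR sweeps use p ≥ t so recall reaches 1;
* batch-norm ε = 10⁻⁵; soft-dice ε = 10⁻⁶;
* Adam β₁ = 0.9, β₂ = 0.999, ε = 10⁻⁸; one shared step counter across
  parameters;
* bilinear upsampling uses the half-pixel (align-corners-false) mapping;
  max-pool backward routes gradients to the stored argmax;
* degenerate inputs: empty-vs-empty masks score 1 (flagged); constant
  CLAHE tiles pass through unchanged; a constant section's Otsu threshold
  is its own value (empty foreground); zero-variance density agreement is
  an error, not NaN.

## Limitations

The engine is CPU-only and single-threaded apart from BLAS; wall-clock
training at the published scale (2048² tiles, depth 4, base 64, 100
epochs) is far outside its envelope — the package targets method-level
correctness, scaled experiments and analysis of already-predicted maps.
Dense overlapping clusters are counted as one region by design, so
densities are biased low in heavily clustered fields; instance-level
splitting is out of scope. The generator's defaults describe one
plausible MBFM-like regime and are not fitted to any particular
instrument.
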