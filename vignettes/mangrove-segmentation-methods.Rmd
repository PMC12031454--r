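---
title: "Methods: attention-based mangrove extent and species segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attention-based mangrove extent and species segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Mangrove forests occupy intertidal zones where field surveys are slow and
satellite pixels are too coarse to separate species. Centimetre-scale
multispectral UAV imagery (five bands: Blue, Green, Red, RedEdge, NIR at a
ground sample distance of 4.61 cm/pixel) makes two segmentation tasks
feasible: mapping mangrove extent against water and bare ground, and labelling
each pixel with one of four classes — the *Aegiceras corniculatum*–*Avicennia
marina* association (gray value 0), *Rhizophora stylosa* (1), *Sonneratia
apetala* (2), and non-mangrove surfaces (3). The red-edge and NIR bands carry
most of the discriminative signal: vegetation is bright there, water is dark,
and the three canopies differ in visible greenness.

This package implements both networks, the tiling and evaluation machinery
around them, and a seeded synthetic-scene generator, because the original
drone imagery is not publicly distributable. Everything here runs on
synthetic data; consequences of that choice are discussed at the end.

# Parallel dual attention

Both networks share one attention block with two independent branches applied
to the same feature map $F$ of shape $H \times W \times C$:

* **Channel (spectral) attention.** Global average- and max-pooling reduce
  $F$ to two $1 \times 1 \times C$ vectors; a shared two-layer perceptron
  (hidden width $C/r$, rectifier activation) maps each; the two outputs are
  summed elementwise and passed through a sigmoid, giving one weight per band
  in $(0,1)$:
  $W_c = \sigma\bigl(\mathrm{MLP}(\mathrm{AvgPool}F) + \mathrm{MLP}(\mathrm{MaxPool}F)\bigr)$.
* **Spatial attention.** Per-pixel mean and maximum along the channel axis
  are concatenated into a 2-channel map and convolved with a $7\times7$
  kernel under symmetric zero padding, then passed through a sigmoid:
  $W_s = \sigma\bigl(f^{7\times7}[\mathrm{AvgPool}F; \mathrm{MaxPool}F]\bigr)$.

The two weightings are combined **in parallel**, not serially:
$X_{att} = W_c \odot F + W_s \odot F$. With both weights frozen at 0.5 the
block is exactly the identity, which the tests exploit. The combination of
the two MLP branches is an elementwise sum (the convention of the attention
module family this block descends from); the reduction ratio defaults to 8
with the hidden width floored at 1.

# MangroveNet (binary extent)

A deliberately lightweight encoder-decoder. The encoder has three stages of
two $3\times3$ convolutions + rectifier, separated by exactly **two**
$2\times2$ max-poolings whose argmax indices are recorded. Three scale views
result; each passes through its own dual-attention block, is projected to the
stage-1 width by a $1\times1$ convolution, upsampled (nearest-neighbour,
doubling once per pooling it underwent), and accumulated onto the un-pooled
stage-1 features — the multi-scale fusion
$X^{total}_{con} = X^0 + \sum_i \mathrm{Up}(X^i_{att})$. The decoder mirrors
the encoder using the recorded indices for unpooling (values return to their
argmax positions, zeros elsewhere). The head projects the fused layer and the
final decoder layer each to one channel with $1\times1$ convolutions, sums
them, and applies the sigmoid; this resolves the scalar logit the
architecture needs but leaves implicit. Training minimizes mean binary
cross-entropy with probabilities clipped to $[10^{-7}, 1-10^{-7}]$.

Pixels with probability $\ge 0.5$ are labelled mangrove; the boundary is
deliberately inclusive and fixed for reproducibility.

# AttCloudNet+ (4-class species)

A deeper encoder-decoder for the harder species task. Each **contracting
block** sums a three-convolution branch (rectifiers after the first two
convolutions) with a parallel $1\times1$ branch and max-pools the sum,
returning the pre-pool sum as a skip. A **feedforward** path projects every
skip to the deepest width, max-pools each to the bottleneck geometry, and
accumulates them. The **expanding** step convolves the feedforward result
twice and adds the bottleneck encoding. Decoding alternates nearest-neighbour
**upsampling blocks** with convolutions, and each level adds a $1\times1$
lateral projection of that level's contracting skip — without these lateral
connections all spatial detail must pass through the bottleneck and held-out
accuracy drops by roughly ten points. Parallel dual attention is inserted at
the bottleneck, between downsampling and upsampling. The head is a
$1\times1$ convolution to $K=4$ channels with per-pixel softmax (the species
labels are mutually exclusive, so a simplex output is the natural choice; the
binary sigmoid formulation covers only $K=2$).

Training minimizes the **filtered Jaccard loss**: one minus the mean soft
Jaccard index $J_k = \sum p_k t_k / (\sum p_k + \sum t_k - \sum p_k t_k)$
over the classes *present* in the tile's ground truth. Filtering means a tile
lacking a class contributes no penalty for it, which protects training
against sparsely labelled tiles; an entirely empty label falls back to
categorical cross-entropy. The exact published formula for this loss is not
restated in the source describing the species network, so the implementation
follows the one property that description fixes — absent-class filtering —
on top of the standard soft-Jaccard form.

Ties in the final argmax break toward the lowest class index, so a fully
uninformative prediction yields class 0 everywhere.

# Optimization

Adam at learning rate $10^{-4}$, batch size 4, at most 1000 iterations; these
are the standard settings for this model family at this scale and are the
package defaults. Gradients are averaged over the batch; shuffling is seeded,
so same-seed runs are bit-reproducible on one platform. When a validation set
is supplied, it is evaluated every 50 iterations and the best checkpoint (by
validation loss) is restored at the end — a bounded-cost model-selection rule
that matters for the Jaccard loss, whose trajectory is not monotone.
Parameters start Glorot-uniform with zero biases, which has the convenient
consequence that an all-zero input tile produces probability exactly 0.5
everywhere (sigmoid of a zero logit), a property the tests assert.

Two numerical hazards are worth recording. First, pure soft-Jaccard training
can collapse a class: once its probability is near zero everywhere, the
gradient of its Jaccard term scales with that probability and recovery within
the iteration cap is effectively impossible. Capacity (a first stage wider
than the five input bands) and the lateral decoder connections avert collapse
on the benchmark seed; some seeds still merge the two spectrally closest
canopies, which is reported honestly by the acceptance script rather than
patched. Global-norm gradient clipping was evaluated against these spikes and
removed: they are a landscape property, not an exploding-gradient one.
Second, pixel counts are accumulated in doubles (exact below $2^{53}$)
because $N^2$ overflows 32-bit integers already at a few dozen tiles.

# Tiling, splitting, mosaicking

Large rasters are cut into $512 \times 512$ windows whose interior anchors
advance by $512 - 150 = 362$ pixels, guaranteeing a 150-pixel overlap between
neighbours; the final window per axis is clamped to the raster edge, so every
pixel is covered by a fully in-bounds window at the cost of a variable edge
overlap (the alternative — padding — would inject synthetic pixels into
training). Labels are tiled with the identical grid, so image/label alignment
is structural. Mosaicking is exact by construction for imagery
(`"overwrite"`); for probability maps, overlapping predictions are averaged
before thresholding or argmax (`"average"`). The train/validation split is a
seeded uniform shuffle taking the first `round(0.8 N)` ids; at the species
task's $N = 10{,}560$ this gives exactly 8448/2112.

16-bit imagery is converted to 8-bit by per-band linear rescaling of
$[\min, \max]$ onto $[0, 255]$ with half-away-from-zero rounding (a constant
band maps to 0), after which tiles are normalized to $[0,1]$ by division by
255 for the sigmoid/cross-entropy numerics.

Multi-band rasters travel as multi-page TIFF (one directory per band, band
order preserved) with a JSON sidecar for band names, bit depth, GSD, and the
geo tag, which passes through I/O untouched; masks are single-band 8-bit
TIFFs holding the gray values directly.

# Evaluation

All metrics are computed from a confusion matrix with **rows = truth,
columns = prediction** (the fixed convention of this package; kappa and
overall accuracy are symmetric in it). The binary suite is accuracy,
precision, recall, F1, and the two-class mean IoU
$\tfrac12\bigl(\mathrm{TP}/(\mathrm{TP}+\mathrm{FP}+\mathrm{FN}) +
\mathrm{TN}/(\mathrm{TN}+\mathrm{FN}+\mathrm{FP})\bigr)$. Cohen's kappa is
$(P_o - P_e)/(1 - P_e)$ with the standard sum-of-products chance agreement
$P_e = \sum_k r_k c_k / N^2$ — a printed variant of this formula multiplies
the four binary marginals instead, which is not a probability (it evaluates
to 600 on a 100-pixel example) and is documented as a deviation. Metrics are
evaluated in single-division rational forms (e.g. kappa as
$(N\,\mathrm{tr} - S)/(N^2 - S)$, F1 as $2TP/(2TP+FP+FN)$, which *is* the
harmonic mean of precision and recall) so they agree bit-for-bit with
integer-arithmetic oracles. Zero-denominator metrics return 0 with an
explicit flag instead of raising, because degenerate tiles are routine in
per-tile evaluation. Kappa values map to qualitative bands that are
upper-inclusive ($0 < \kappa \le 0.2$, ..., $0.8 < \kappa \le 1$), with the
exact values $-1$, $0$, $+1$ carrying their own labels; the scale does not
subdivide $(-1, 0)$, which this package labels "Worse than random".

# Area accounting

Class areas are pixel counts times the squared ground resolution,
$S_j = n_j (r/100)^2$ m² at $r$ cm/pixel. Agreement with a manually
delineated reference is summarized by the per-class relative error
$|S_{D} - S_{M}|/S_{D}$; the printed summary statistic for this comparison is
its complement, $100(1 - \overline{e})$ percent, and the implementation
reports both the mean error and that accuracy percentage (the formula as
printed computes the error, while its reported value is the accuracy — both
fields are exposed so neither reading is lost). The measure is
scale-invariant, and classes with zero reference area are excluded with a
flag.

# The synthetic scene generator

`generate_scene()` emulates what matters for these methods: spatially
contiguous class regions with class-distinct band signatures. A mask is drawn
by per-pixel argmax over per-class random Gaussian-bump score fields (giving
blob-shaped, contiguous regions); the raster is per-class band means plus
Gaussian noise (sd 8 gray levels by default), rounded and clipped to 8-bit.
Default signatures encode the documented qualitative contrasts: *Rhizophora*
darkest green with the highest NIR (40/80/50/120/185 across B/G/R/RE/NIR),
the *Aegiceras–Avicennia* association slightly lighter (60/110/70/130/170),
*Sonneratia* lightest (80/150/100/160/160), and "other" spectrally flat with
low NIR (90/95/90/80/40). These were chosen once as plausible 8-bit levels
honouring those orderings; they are deliberately separable (several noise
standard deviations apart), because the benchmark's purpose is to verify that
the networks and training loop work, not to estimate field performance.
Optional shadows darken a controlled fraction of vegetated pixels by a single
multiplicative factor (0.45) in contiguous blobs across all five bands —
reproducing the way real canopy shadows acquire gray values close to the dark
classes — and default to off.

What the generator does **not** model: canopy texture, within-class spectral
gradients, mixed pixels at boundaries beyond the hard label edge, sensor
noise correlation between bands, and radiometric variation across a scene.
Passing the synthetic benchmarks therefore demonstrates correctness of the
implementation and learnability under clean conditions; it does not predict
accuracy on real drone imagery.

# Benchmark problem sizes

The seeded benchmarks (`synthetic_benchmark()`) train on 60 tiles of
$32\times32$ pixels (48 train / 12 validation by the 80/20 split), MangroveNet
at widths 8/16/32 and AttCloudNet+ at depth 4, widths 8/16/32/64, for at most
1000 iterations at the standard optimizer settings. These sizes were chosen
so a full two-task run completes in a few minutes on one CPU while leaving
the optimization problem non-trivial. The spec-style small widths (4/8/16/32)
remain in the unit tests; the benchmark uses a first stage wider than the
five input bands because a narrower one bottlenecks the spectra and makes
class collapse under the Jaccard loss much more likely.

# Known limitations

* The networks are trained from scratch without normalization layers; at the
  fixed learning rate some seeds converge to a solution that merges the two
  closest canopy classes (see Optimization). Best-checkpoint retention
  mitigates but cannot repair a class that was never learned.
* The tiling module holds rasters in memory; scenes far beyond the study's
  ~13k x 15k pixels would need windowed I/O.
* GeoTIFF georeferencing is carried as an opaque sidecar tag, not
  interpreted; reprojection and geo-correction are out of scope.
* The species benchmark's headline numbers are specific to the synthetic
  conditions above and to the seed; they are not comparable to results on
  real imagery.
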