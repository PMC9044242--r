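---
title: "Hard-example weighting and the double-branch fusion U-Net: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard-example weighting and the double-branch fusion U-Net: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselseg)
```

## The problem

Retinal vessel segmentation (RVS) assigns every pixel of a fundus
photograph to vessel or background, restricted to the circular field of
view (FOV). Most pixels are easy; performance is decided by a minority of
*hard* pixels — thin vessels, vessel edges, optic-disc edges, lesion
areas — where a trained model's output probability hovers near 0.5. The
class balance is also skewed: roughly one vessel pixel per nine
background pixels inside the FOV, which is why accuracy alone is a poor
summary (an all-background prediction already scores 90%) and why F1,
G-mean and MCC carry the evaluation.

This package implements a training strategy built around three
components.

## Hard-example masks by morphology

The classical way to find hard pixels is to run a rough segmentation
model and band-threshold its probability map near 0.5
(`probabilityBandMask()`). That requires training an extra model. The
approach implemented here derives the mask from the ground-truth label
alone with two binary morphological operations:

$$B = \mathrm{erode}(L), \quad C = L \setminus B, \quad
  D = \mathrm{dilate}(C), \quad M = D \setminus B.$$

Erosion removes everything a structuring element does not fit inside, so
$B$ is the easy interior of thick vessels; $C$ keeps vessel edges and
whole thin vessels; dilating $C$ adds the adjacent background band
(where false positives concentrate) but re-includes some interior
pixels, which the final subtraction removes. Two invariants
characterize the construction and are enforced by tests: the mask never
overlaps the eroded core ($M \wedge B = 0$), and every thin-structure
positive is covered ($L \setminus B \subseteq M$).

The mask feeds a per-pixel weight map $W_h = M \cdot w + 1$ and the
weighted cross-entropy

$$\mathcal{L} = -\frac{1}{N}\sum_i \big[y_i \log \hat y_i +
  (1-y_i)\log(1-\hat y_i)\big]\, W_{h,i}.$$

Design notes:

* The structuring element is configurable (`square`, `cross`, `disk`;
  any radius) for both the erosion and the dilation step, since label
  resolution varies across datasets. The default is a 3×3 square for
  both, which reproduces the visual band width of one-to-two pixels
  around vessel boundaries at DRIVE-like resolution.
* Out-of-image pixels are treated as background in both operations — the
  conservative, standard convention. A consequence worth knowing: the
  duality $\mathrm{dilate}(A) = \neg\,\mathrm{erode}(\neg A)$ holds only
  away from the border, where the convention is invisible.
* The weight hyperparameter $w$ defaults to 2 (hard pixels count three
  times as much as easy ones). This is a package default, exposed as
  `weightHyper`; $w = 0$ reduces the loss to plain cross-entropy, which
  tests use as an identity check.
* The mask is computed from the *augmented* label during training, so
  mask and label can never drift apart geometrically.

## Random channel attention (RCA)

RVS datasets are small (tens of images), so regularization matters. RCA
multiplies each feature channel by a freshly sampled random weight
during training and is the identity at inference. Unlike learned channel
attention the weights carry no information; like dropout the noise
discourages co-adaptation, but channels are softly rescaled rather than
zeroed.

The weight distribution is specified by its first two moments: mean 1,
variance 0.5. The distribution family is not further constrained, so the
package uses a Gaussian, clipped symmetrically to $[0, 2]$: symmetry
preserves the mean, and the clip excludes sign-flipping negative
weights. Weights are resampled per forward pass and per instance, the
reading that maximizes the stochastic-regularization analogy. Because
the mean is 1, no inference-time rescaling is needed (contrast inverted
dropout). With variance 0 RCA degenerates to the identity in both modes,
which is also how the deterministic gradient checks run.

## The network

`buildDbfuNet()` assembles a U-Net-family architecture with four named
parameter groups:

* **encoder** — a convolutional stem, then `depth` stages of
  (residual block, stride-2 downsampling convolution), then a residual
  bottleneck. Channels double per stage from `baseChannels`.
* **decoder1**, **decoder2** — structurally identical decoders; each
  stage is nearest-neighbor 2× upsampling, a convolution unit, an
  *additive* skip connection from the matching encoder stage
  (LinkNet-style), and a residual block. Each decoder ends in a 1×1
  convolution + sigmoid head.
* **fusion** — concatenates the two decoders' final feature maps, runs
  one residual block (whose 1×1 projection absorbs the channel
  doubling), and produces the final head with a 1×1 convolution +
  sigmoid.

Every residual block contains an RCA step on the transformed features,
applied just before the identity addition so the residual path stays
clean. Convolution units are convolution → per-channel (instance)
normalization → ReLU; convolutions feeding a normalization carry no bias.
Instance normalization was chosen over batch statistics because the
prescribed batch size is 2, where batch statistics are noisy, and
because it makes evaluation deterministic without running-average state.
All weights are he-normal initialized under a caller-supplied seed.

The three heads are supervised separately (deep supervision): decoder 1
with plain cross-entropy, decoder 2 with the hard-example-weighted loss,
fusion with cross-entropy. Focal loss ($\gamma = 2$) and dice loss
($\varepsilon = 10^{-5}$) are implemented as drop-in alternatives for
decoder 2, as comparison arms.

The engine underneath is a small hand-written CNN stack (im2col +
BLAS-backed convolutions with explicit backward passes). Every layer's
gradient is verified against central finite differences, and the whole
model passes an exhaustive per-leaf finite-difference sweep on a reduced
configuration; near ReLU kinks the comparison is made with a combined
absolute/relative tolerance because subgradients make exact agreement
there undefined.

## Preprocessing and augmentation

The network consumes the green channel (highest vessel contrast),
enhanced by CLAHE (clip limit 2, 8×8 tiles — the de-facto literature
defaults, both exposed), rescaled to $[0,1]$, and zero-padded on the
bottom/right so each side is divisible by $2^{\mathrm{depth}}$ (32 at
full depth). Label and FOV are padded with zeros, so padded pixels carry
no vessels and can never enter FOV-restricted metrics; `cropToOriginal()`
inverts the padding exactly. The order green → CLAHE → rescale follows
the listing order of the steps in the method description; CLAHE
parameters are not prescribed there.

Training-time augmentation applies one shared geometry per sample to
image (bilinear), label and FOV (nearest neighbor): rotations from
{0°, 90°, 180°, 270°} with ±15° jitter, horizontal mirroring,
translations up to 8 px, and Simard-style elastic deformation (uniform
random displacement fields, Gaussian-smoothed at scale `sigma`, peak
magnitude `alpha`; defaults 8 px and 8 px at 128-px image scale, elastic
applied with probability 0.5). Zero-fill from rotation is masked by the
transformed FOV. The trainer draws one fresh augmentation per sample per
epoch; multiplicity is a config choice since none is prescribed.
Augmentation never runs at evaluation time.

## Staged training

Training proceeds in three phases (five segments), with per-group
freezing:

1. encoder + decoder 1, plain cross-entropy, 12 epochs;
2. decoder 2 (he-normal re-initialized at phase start) with the
   weighted loss, encoder frozen, 12 epochs; then all parameters
   fine-tuned 8 epochs at 5e-5;
3. fusion (freshly initialized) with everything else frozen, 6 epochs;
   then all parameters fine-tuned 4 epochs at 5e-5.

SGD uses batch size 2 and momentum 0.9 (momentum itself is a package
default; 0.9 is the usual choice in this literature). The base learning
rate 7e-4 is multiplied by 1/3 at each third *of the segment* — the
schedule's natural period is ambiguous as stated ("every 1/3 epoch"
would decay by $3^{-36}$ over 12 epochs and numerically annihilate the
rate), so the package reads it per segment, giving three decay steps.
During fine-tune segments the losses of all heads trained so far are
summed, since the head set is not prescribed there. 10% of the training
samples are held out for validation; each segment keeps the parameters
of its best-validation-loss epoch. `kfoldSplit()` provides the 5-fold /
4-fold protocols used for datasets without official test splits.

## Evaluation protocol

Probability maps are rescaled to integer gray maps in $[0, 255]$,
binarized at a global threshold, and scored by pooled (micro-averaged)
confusion counts over all test images, using only FOV pixels. The
optimal threshold is the argmax of pooled F1 over all 256 levels on
validation data, ties broken toward the lowest threshold; binarization
uses `>=`. Metrics: F1, Se, Sp, Acc, G-mean, MCC, and rank-based
(Mann–Whitney) AUC with ties counted half, computed on the continuous
maps. MCC defaults to the standard Matthews coefficient; a non-negative
"as-printed" variant found in parts of the RVS literature (numerator
$TP \times TN$) is available behind `mccVariant = "as-printed"` because
tabled values cannot disambiguate which was used. Degenerate
denominators report 0 rather than NaN.

## The synthetic testbed

`generateFundusDataset()` builds seeded fundus-like samples: random-walk
vessel trees with stochastic bifurcation rooted near an optic-disc
position, rasterized with disk brushes tapering from ~6 px trunks to
1 px tips; a brighter textured background (smooth illumination field +
Gaussian noise); a sharp-edged bright disc; optional lesion-like blobs;
all inside a circular FOV, with vessels darker in the green channel.
Secondary branches are grown until the vessel fraction inside the FOV
reaches its target (default 0.10, the ~1:9 ratio of the clinical
datasets), which also makes the realized fraction monotone in the
target.

What it does *not* emulate: central light reflexes inside vessels,
inter-image color variation, camera vignetting beyond the smooth field,
genuine pathology textures, or annotation noise. Passing tests on this
testbed therefore demonstrate that the pipeline's machinery — masks,
losses, staged optimization, metrics — behaves as specified, not that
the package reaches clinical-benchmark accuracy; the published-benchmark
numbers shipped in `publishedBenchmarks()` are used only for metric
self-consistency checks.

## Desk-scale sizing

The problem sizes used by the tests and the acceptance script are a
deliberate package choice so the full pipeline runs on one CPU core: a
depth-3, 8-channel model on 32 synthetic 128×128 samples (8 held out)
for the end-to-end recovery experiment, 16 samples for the
decoder-threshold comparison, and 4 samples at 64×64 for the schedule
smoke test. At this scale an epoch contains ~15 minibatch updates, three
orders of magnitude fewer than an augmented clinical training run, so
`scaledStagedConfig()` uses proportionally larger learning rates (4e-2
main, 3e-3 fine-tune) and shorter segments (8 / 6+3 / 5+2 epochs); the
full-benchmark defaults remain on `stagedTrainConfig()`. On this testbed
the fusion head reaches F1 ≈ 0.85 on held-out samples, and the
hard-example-weighted decoder's optimal threshold sits at or above the
plain decoder's — the qualitative signature of the training strategy.

## Numerical choices

* Probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before logs.
* Loss reduction is mean-over-pixels (keeps learning rates comparable
  across image sizes); dice is inherently global. The loss runs over
  all padded pixels by default (padded pixels have zero label and weight
  1); `lossInFov = TRUE` restricts it, since only the *metrics* are
  FOV-restricted by protocol.
* Normalization epsilon $10^{-5}$; sigmoid logits clamped at ±40 before
  exponentiation.
* Gray rescaling uses round-half-up; reported tables round metrics to 4
  decimals.
* Random streams: every public entry point takes a seed; sub-seeds are
  derived arithmetically (modulo $2^{31}-1$) so results are independent
  of call order.

## Known limitations

* Instance normalization departs from the (unspecified) normalization of
  the reference architecture; with batch size 2 it is the stabler
  choice, but absolute benchmark parity is out of scope on CPU anyway.
* The engine is single-threaded and double-precision; full-resolution
  clinical training is possible but slow (the CLI accepts DRIVE-style
  directories for users who want to try).
* Elastic deformation resamples labels by nearest neighbor; very thin
  (1 px) structures can locally break or thicken, which is also true of
  the common reference implementations of this augmentation.
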