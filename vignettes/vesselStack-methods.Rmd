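---
title: "Methods: stacked ensemble segmentation of retinal vessels"
author: "vesselStack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked ensemble segmentation of retinal vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Retinal blood vessels change early in diabetic retinopathy, glaucoma and
hypertensive retinopathy, and their manual delineation in fundus photographs
is slow and expert-bound. Automatic segmentation is hard for exactly the
reasons the images are clinically useful: vessels thin out to one or two
pixels, contrast against the retinal background is poor, and the field of
view (FOV) — the circular region the camera actually images — is surrounded
by black border. vesselStack treats the task as pixel-wise binary
classification: given an H×W×3 fundus image in [0, 1], predict for every
pixel the probability that it belongs to a vessel.

## The four base architectures

All four networks share one contract — input H×W×3, output H×W×1 strictly in
(0, 1) via a 1×1 convolution with sigmoid, spatial size preserved — and one
width dial, `baseChannels`: every layer's width scales proportionally, so a
reduced-width model is topologically identical to the full-size one. The
canonical widths use `baseChannels = 64`.

**U-Net** (`buildUnet`). `depth` encoder levels of two 3×3 convolutions with
ReLU followed by 2×2 max pooling, channel count doubling per level; a
two-convolution bottleneck; a mirrored decoder using 2×2 stride-2 transposed
convolutions, concatenation of the matching encoder feature map (the skip
connection), and two 3×3 convolutions per level. Batch normalization is off
in this family — the plain conv+ReLU blocks are the classical design, and at
desk-scale batch sizes batch statistics are noisy.

**Customized ResNet50** (`buildResnet50Seg`). The standard ResNet50 encoder:
a 7×7 stride-2 stem, 2×2 max pooling, then four stages of bottleneck
residual blocks (3, 4, 6, 3 of them; 1×1–3×3–1×1 convolutions with batch
norm, ReLU, and projection shortcuts where shape changes), giving feature
taps at strides 2, 4, 8, 16 and 32. Between encoder and decoder sits a
pyramid pooling module: parallel 3×3 convolutions with dilation rates
`ppmDilations` (default 1, 2, 4), concatenated and fused by a 1×1
convolution. The module is implemented as dilated (atrous) branches: the
bottleneck map at 256×256 input is only 8×8, so small rates are the ones
that still see distinct context windows. The decoder performs five ×2
upsampling steps with skip connections from the stem and the first three
stages.

**U-Net with ResNet50 backbone** (`buildUnetResnetBackbone`). The same
encoder taps feed a U-Net-style decoder (transposed convolution, skip
concatenation, double 3×3 convolution). Four taps (strides 16, 8, 4, 2)
enter the five-level decoder; the final level upsamples without a skip since
no full-resolution features exist in a ResNet encoder. This is the
transfer-learning variant: `loadBackboneWeights()` can restore externally
trained encoder tensors and `freezeParameters(model, "enc.")` excludes the
encoder from updates. No weights ship with the package; everything builds
and trains offline with seeded random initialization
(`pretrainedBackbone = FALSE`, the default).

**Transformer-bottleneck U-Net, CTU-Net** (`buildCtuNet`). Identical to
U-Net except at the bottleneck, where convolutions cannot model the
long-range continuity of vessel trees. The deepest map is projected by a
1×1 convolution to the bottleneck width (`2^depth * baseChannels`, e.g. 128
at base 8 / depth 4), flattened to one token per spatial position (16×16 =
256 tokens at 256×256 input), given a learned positional embedding, and
passed through pre-norm transformer blocks — multi-head self-attention plus
a feed-forward of `mlp_ratio` times the width, each with residual connection
and layer normalization — before being reshaped back for the U-Net decoder.
The transformer hyperparameters are the smallest standard configuration
that lets every token attend to every other: 2 blocks, 4 heads, MLP ratio 4,
learned positions. Head count must divide the embedding width.

Decoder upsampling defaults to transposed convolutions; `upsampling =
"bilinear"` switches to fixed bilinear ×2 interpolation followed by a 3×3
convolution, the common alternative.

## The stacking meta-model

Each trained base model k produces a probability map P_k(x). The maps are
concatenated channel-wise into the feature tensor

    Z(x) = [P_1(x), P_2(x), ..., P_K(x)]

(`stackPredictions`; the channel order is part of the object and is fixed
package-wide to unet, resnet50_seg, ctu_net, unet_resnet_backbone). A small
convolutional meta-model g maps Z(x) to the final prediction

    P_final(x) = g(Z(x))

with architecture 3×3 convolution (64 filters, same padding, ReLU) followed
by a 1×1 convolution (1 filter) with sigmoid. The hidden 3×3 layer carries
no bias term — the following layer's bias absorbs any offset — which makes
the head exactly 3·3·K·64 + 64 + 1 = 2369 parameters at K = 4. The hidden
activation is ReLU, the package-wide default nonlinearity. The meta-model
consumes post-sigmoid probabilities, not logits, because the bases' outputs
are the segmentation masks being fused.

Meta training (`trainMetaModel`) minimizes pixel-wise binary cross-entropy
against the ground truth. The bases are frozen: their predictions are
computed once in inference mode, and only the 2369 meta parameters are
updated — the tests assert the base parameters are bit-identical before and
after. The meta-model is trained on base predictions over the *training*
split; no held-out stacking set is carved out. This carries a known
overfitting risk (the bases have already fit those images), which is
acceptable here because the meta-model is tiny relative to the pixel count;
K-fold out-of-fold stacking would be the defensive extension.

`runAblation` trains one meta-model per base-model subset and emits one
report row per subset; the default list is the ten combinations over four
models (five pairs, four triples, the full quadruple). Each subset uses a
fresh seeded initialization derived from the training seed only, so
duplicated subsets reproduce identical rows.

## Evaluation metrics

All metrics are computed over the pooled pixels of the evaluated images
(micro-averaging) — the dominant convention for the DRIVE/STARE benchmarks —
rather than averaging per-image scores. With TP/TN/FP/FN counted at a
threshold (default 0.5; the choice is exposed everywhere it is consumed):

* accuracy = (TP + TN) / total
* sensitivity SN = TP / (TP + FN), specificity SP = TN / (TN + FP)
* precision = TP / (TP + FP), F1 = 2·precision·SN / (precision + SN)
* BCE = −(1/N) Σ [y log p + (1 − y) log(1 − p)], probabilities clipped to
  [1e−7, 1 − 1e−7] (the common framework epsilon)
* AUC is the Mann–Whitney rank statistic — the probability that a random
  vessel pixel outscores a random background pixel, ties counted ½ — which
  equals trapezoidal ROC integration and is invariant under monotone
  transforms of the scores. Single-class truth raises an error rather than
  silently returning a value; an optional seeded pixel subsample bounds the
  cost on large pooled sets.

Ratio metrics with empty denominators (e.g. specificity when no negatives
exist) are defined as 0 and flagged in the report instead of returning NaN,
so batch evaluation never aborts. Metrics are computed over *all* image
pixels, not restricted to the FOV circle: whether published DRIVE/STARE
tables mask to the FOV is often unstated, and including the black exterior
inflates specificity and accuracy; this choice is deliberate and must be
kept in mind when comparing absolute numbers.

## The synthetic data generator

Real DRIVE/STARE images cannot be redistributed, so the package generates
its own supervision. The generator is not a photorealistic simulator; it
reproduces the statistical structure that makes vessel segmentation what it
is:

* **Vessel trees** (`generateVesselMask`): a recursive random walk. Roots
  start on the FOV boundary heading inward; each step perturbs the heading
  by Normal(0, `angleJitterSd`) and rasterizes a rectangular stroke of the
  current width; with probability `branchProb` a child spawns at 20–50° with
  width multiplied by `widthDecay`. Walks stop at `maxDepth` steps, below
  `minWidth`, or on leaving the image. Width decay at branches produces the
  thin distal vessels that make the task hard. Default parameters scale with
  image size (at 256×256: 4 roots, 40 steps of ~6 px, root width ~5 px,
  decay 0.75) and give masks with vessel fractions well inside (0, 0.35) —
  vessels are sparse, as in real fundus images.
* **Rendering** (`renderFundusImage`): black outside the circular FOV
  (radius fraction 0.95); inside, a base level (0.55) plus a linear
  illumination ramp (amplitude 0.08), minus `vesselContrast` (0.35) times a
  lightly blurred mask, plus Gaussian noise (sd 0.03), clipped to [0, 1];
  red channel at full intensity with green/blue attenuated to mimic fundus
  tint. The blur makes vessel edges soft rather than binary, as in
  photographs.
* **Augmentation** (`augmentSample`): one geometric draw per call —
  rotation in ±15°, x/y shifts in ±10% of each dimension (independent per
  axis), zoom uniform in [0.8, 1.2] (the symmetric reading of a 20% zoom
  range, matching the Keras `zoom_range` convention), horizontal flip with
  probability ½ — applied with the same geometry to image (bilinear) and
  mask (nearest-neighbour, re-binarized at 0.5). Out-of-range regions fill
  with 0, matching the dark FOV exterior. Augmentation is applied on the
  fly during training only (never to validation/test images, never
  materialized to disk).

What the generator does *not* emulate: optic disc and fovea, lesions,
inter-image color variation, JPEG artifacts, annotator disagreement.
Passing tests on synthetic data therefore demonstrate that the machinery —
gradient flow, protocol, stacking — is correct, not that any particular
accuracy will transfer to real fundus photographs.

## Training protocol

`trainConfig()` defaults encode the reference protocol: Adam, learning rate
0.01, 500 epochs, batch size 32, `steps_per_epoch = max(1,
floor(n_train/batch_size))` (20 training images with batch 32 clamp to one
step per epoch), validation at the end of every epoch, and a checkpoint of
the parameters at the best validation loss — ties broken by the *first*
epoch attaining the minimum. The validation set is the test split: the
protocol defines no third split, and this leakage (model selection on the
reporting set) is inherited knowingly; pass a dedicated validation split to
`trainSegmentationModel` if honest model selection matters. The meta-model
trains under the same hyperparameters by default.

Experiments driven by `runExperiment()` default to a single data source, but
`images_dir`/`masks_dir` accept parallel lists, in which case the datasets
are pooled before splitting (ids are prefixed per source). This supports
the pooled-training reading of multi-dataset protocols; per-dataset
training — one experiment per dataset — remains the default interpretation.

Randomness is compartmentalized: parameter initialization draws from the
architecture seed, epoch shuffling and augmentation from per-epoch streams
derived from the training seed, and the generator from its own seeds. Every
`withr::with_seed` block restores the global RNG, so package calls never
perturb a user's random stream, and a rerun with identical configuration
reproduces reports byte for byte on one device. Non-finite losses abort
with an error naming the epoch and step rather than training through NaNs.

## Desk-scale profile and numerical choices

The package's own experiments (tests, the acceptance script) run a reduced
profile chosen once: 64×64 images, `baseChannels` 2–8, learning rate 1e−3
to 2e−3, batch size 4, 30 epochs on 40 training / 10 test synthetic images.
Width scaling preserves topology, so these models exercise every layer type
of the full-size networks; the lower learning rate is used because Adam at
0.01 is unstable at widths this small. The ensemble benchmark
(`syntheticEnsembleBenchmark`) trains all four bases and the meta-model
under this profile; across seeds the stacked model's test F1 consistently
matches or exceeds the best single base, which is the property the design
is meant to deliver. Small batches were preferred over large ones at fixed
epochs because the clamp rule ties optimizer steps to `n_train/batch_size`:
at 40 training images, batch 4 gives 300 updates in 30 epochs versus 37 at
batch 32, and the tiny models are update-starved otherwise.

Other numerical decisions:

* Probability clipping at 1e−7 in the loss; the gradient uses the same
  clipped value, keeping updates finite even for saturated sigmoids.
* Mask binarization after any interpolation at 0.5; nearest-neighbour on a
  clean 0/1 mask cannot create intermediates, so this only guards against
  anti-aliased files.
* Batch-norm running statistics with momentum 0.9; inference always uses
  running statistics, making evaluation deterministic.
* He initialization for convolutions, Glorot for attention/MLP weights,
  zeros for biases, sd 0.02 for positional embeddings.
* The checkpoint comparison is strict (`<`), which implements the
  first-best tie-break.

## Known limitations

* No GIF decoding (some public vessel datasets ship GIF masks); convert to
  PNG first. PNG/JPEG/TIFF and PPM/PGM are read natively.
* The autodiff engine is dense and single-device; full-size (base 64,
  256×256, 500-epoch) training is possible but slow on one CPU — the design
  target is correctness and desk-scale reproducibility, with the full
  protocol expressed in configuration rather than demonstrated in tests.
* Whole-image (non-FOV-masked) metrics overstate specificity/accuracy
  relative to FOV-restricted evaluation protocols.
* STARE provides two annotators; the loader takes whichever mask directory
  it is pointed at and applies no hidden preference.
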