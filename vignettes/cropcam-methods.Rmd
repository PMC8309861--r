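---
title: "Weakly supervised crop-area segmentation: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised crop-area segmentation: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A combine harvester works a field by cutting along the edge of the still-standing
crop; the operator steers by watching the boundary between the uncut crop and the
freshly harvested stubble in the front field of view. Automating that perception
means (i) segmenting the uncut crop area in the camera frame and (ii) reducing the
segmented region to one straight guidance line — the uncut crop edge.

Fully supervised semantic segmentation needs dense pixel labels, which are both
laborious and genuinely ambiguous at the ragged crop boundary, and harvest footage
is too self-similar to yield many independent training frames. `cropcam` instead
implements a *weakly supervised* pipeline: the only supervision is an image-level
class label on class-pure sub-images, and pixel-level localization falls out of the
classifier's own class activation maps (CAMs).

## The model

The backbone is a deliberately shallow classifier: four 3×3, stride-1,
same-padding convolution blocks with ReLU, with 2×2 max-pooling after blocks 1–3,
ending in $K = 256$ feature maps $f_k(x,y)$ at 1/8 of the input resolution.
Channel widths are 32→64→128→256. Three pooling stages are the only arrangement
consistent with "four conv blocks" and "final maps at 1/8 size"; channel widths
and kernel size are our choice (the final map count and scale are the binding
constraints, and 3×3 stride-1 blocks are the standard minimal texture extractor).

A global-average-pooling (GAP) head reduces each map to its mean score

$$G_k = \frac{1}{N}\sum_{x,y} f_k(x,y),$$

and a bias-free linear layer $\omega \in \mathbb{R}^{3\times 256}$ followed by a
softmax turns the 256 scores into probabilities for the three scene classes
(background, uncut crop, harvested). The head has *no* bias so that the class
activation map

$$M_c(x,y) = \sum_k \omega^c_k\, f_k(x,y)$$

reproduces the classifier's logits exactly under spatial averaging:
$\mathrm{mean}_{x,y}\, M_c = (\omega G)_c$. This identity is asserted in the test
suite to 1e-5; it is what makes the CAM a faithful spatial decomposition of the
classification decision rather than a heuristic saliency map.

At test time a full scene (resized so that both sides are divisible by 8) is
pushed through the same weights; the per-class CAMs are converted to per-pixel
probabilities by a categorical softmax applied pixel by pixel,

$$P_c(x,y) = \frac{\exp M_c(x,y)}{\sum_{c'} \exp M_{c'}(x,y)},$$

each probability channel is upsampled bilinearly to the inference resolution, and
every pixel takes its argmax class. The crop-class mask is cleaned by 8-connected
component labeling, removing components smaller than `min_area`.

### Order of softmax and upsampling

The softmax is applied at native CAM resolution *before* upsampling, and the
interpolation is plain separable bilinear with pixel-center alignment. Because
linear interpolation is applied channelwise with shared weights, per-pixel channel
sums remain exactly 1 after upsampling — normalization is conserved by
construction, not renormalized after the fact. Upsampling the CAMs first and
softmaxing afterwards would differ slightly (softmax does not commute with
averaging); we chose softmax-first because it preserves the probabilistic
interpretation at every scale. The resampling routines are written in the package
(a 20-line weight-matrix product) so that this conservation property and the
pixel-center registration of masks back to frame coordinates are exact and
testable, rather than depending on an external library's undocumented sampling
grid.

## Training

Patches enter the net as random square crops (the training `input_size`) of the
class-pure windows; validation uses deterministic centre crops. The loss is the
mean squared error between the softmax output and the one-hot label — MSE paired
with a softmax output layer, with the gradient taken through the softmax.
Optimization is Adam with learning rate 1e-4 and batch size 64. Training halts
when the validation loss has not reached a new minimum for `patience` epochs
(default 10; the desk-scale pipeline uses 8) and the returned weights are those of
the best epoch, so the delivered model sits at the lowest validation cost.
Gradients are computed by our own backward pass (im2col + GEMM in C++); the
analytic gradients are verified against central finite differences in the test
suite, which is the strongest available correctness oracle for the training path.

All randomness — weight initialization (Kaiming fan-in scaling for conv layers,
zero-mean 0.01-s.d. for the head), epoch shuffling, crop draws — flows from one
seed through named substreams, so training is bit-reproducible.

## The synthetic scene generator

Desk-scale development and testing need scenes with *known* ground truth. The
generator emulates the front-view structure of a harvest scene with three regions
separable by local colour and texture, which is exactly (and only) the cue a
patch-trained classifier can exploit:

* **uncut crop**: dense 1–2 px vertical strokes in a green–yellow family with
  per-stroke hue jitter and occasional darker strokes;
* **harvested stubble**: horizontal stripes (3 px) in a brown family with
  speckle;
* **background**: a smooth vertical sky gradient plus noise.

The crop/harvested boundary is a near-vertical line (|lean| ≤ 30°) parameterized
by its bottom-row intersection and its signed angle from the image vertical;
the ground truth is stored both as a ρ–θ line and as the crop polygon. The crop
mask is produced by rasterizing that polygon with the package's even-odd
pixel-centre scanline rasterizer — the *same* rasterizer used to rasterize ground
truth inside the IoU metric, so no rasterizer bias can enter the evaluation, and
the "polygon rasterizes exactly to the mask" invariant holds by construction.
Sequences drift the boundary position and angle per frame (seed offset = frame
index), emulating the shrinking uncut area as the harvester works.

What the generator does **not** emulate: perspective distortion, the harvester's
header in frame, illumination changes, weather, crop species diversity, and the
fine stem-level structure that makes real boundaries ragged. Passing tests on
synthetic scenes therefore demonstrate the correctness of the machinery (shapes,
equations, geometry, training dynamics, metric arithmetic) and the method's
behaviour under its own assumptions — not field performance. Field-scale accuracy
claims require field footage.

## Patch extraction rules

One patch per class per frame, matching the arithmetic that 480 frames yield
1440 patches, 480 per class. The window search returns the exact largest
fully-pure axis-aligned rectangle subject to both sides being at least
`crop_size` (histogram-of-heights algorithm restricted to admissible candidates;
ties broken topmost-then-leftmost, so extraction is deterministic). Purity
thresholds are 1.0 for background and harvested and 0.95 for crop: crop
boundaries are ragged in real imagery, so when no fully-pure window of
admissible size exists the crop window may grow from the pure core by a
deterministic greedy 1-px expansion while window purity stays ≥ 0.95. A frame
in which some class still admits no window is skipped and logged. The
train/validation split alternates by frame index (even→train, odd→val): a
deterministic realization of a half/half split whose halves differ by at most
one patch per class.

## Edge detection

The mask's outer contour is taken as the morphological boundary: mask pixels
with a 4-neighbour outside the mask or on the image border. On a binary mask
this coincides with the contour a Canny detector traces on the 0/255 rendering
(there is no gradient ambiguity on a two-level image); the suite pins the
implementation to an independent per-pixel oracle. The contour is then trimmed:
rows in the top and bottom 10% of the contour's *own* row extent (not the image
height — the trim is relative to the contour area) are dropped, and each
remaining row keeps its maximum-x pixel, isolating the right-hand side of the
region — the side in contact with the harvested area.

A ρ–θ Hough accumulator over those pixels uses 1 px × 1° bins with θ restricted
to ±45° about the vertical-line normal (the task geometry guarantees a
near-vertical edge) and a vote threshold of 30% of the filtered pixel count.
All cells reaching threshold are averaged into a single line: ρ by weighted
mean, θ by vote-weighted circular mean with period 180°. Vote weighting matters
at the edges of the θ window, where quantization neighbours exist on one side
only and an unweighted mean would bias the angle by over a degree. On noiseless
ground-truth masks the detector recovers the generator's line within 2 px at
the bottom row and 1° in angle across the admissible geometry range; when the
true edge leaves the frame the detected line collapses to the image border,
which is the correct degenerate answer.

## The patch-classification baseline

The comparison baseline tiles the frame into complete 80×80 patches, classifies
each tile, and takes the union of crop tiles; residual border strips narrower
than a tile are labeled background. Whether this baseline should share weights
with the CAM model was an open design choice; we share them — the backbone is
fully convolutional and the GAP head is size-agnostic, so the same trained
weights classify any tile whose sides are divisible by 8. This isolates the
*resolution* difference between patch-level and pixel-level inference from any
difference in feature quality, which is the comparison of interest. The tile
mask is constant on 80-px blocks, producing the characteristic step-shaped
right boundary and a substantial IoU deficit against the CAM segmentation of
the same scenes.

## Metrics

* **IoU** against the polygon ground truth by exact pixel counting, with the
  polygon rasterized by the package's own rasterizer at mask resolution
  (empty ∪ empty is defined as IoU 1).
* **Lateral error**: signed horizontal distance between the bottom-row
  intersections of the estimated and true edge lines, divided by image width.
* **Angular error**: absolute difference of vertical-axis angles, wrapped into
  [0°, 90°].

Per-frame tables keep the lateral sign; summary rows report means of absolute
values (signed means can cancel and understate the error). Frames where
segmentation or line fitting fails are recorded with the reason and excluded
from summaries, whose n is reported alongside.

## Desk-scale study conditions

The default pipeline configuration is the package's reference experiment,
chosen once:

* an 80-frame sequence of 180×180 scenes, horizon at row 68, boundary starting
  at x = 118 with −6° lean, drifting −0.45 px and +0.15° per frame (so the
  uncut area shrinks and the lean sweeps through vertical to +6°);
* pixel noise σ = 6 on the 0–255 scale;
* the first 60 frames train (in-order split, as a recorded harvest would be
  used), the last 20 are held out;
* training crop size 64 px — the largest multiple of 8 that all three class
  regions admit across the whole drift range at these scene sizes;
* inference at 176 px (the largest multiple of 8 below the 180 px frame; the
  fully convolutional backbone accepts any such size, and inferring near
  native resolution keeps the CAM grid fine relative to the crop region);
* component filter `min_area` = 0.5% of frame pixels;
* Adam 1e-4, batch 64, patience 8, at most 40 epochs.

On one CPU the full pipeline (generation, dataset, training, evaluation of both
methods) takes roughly two minutes. Dataset-arithmetic checks that need 480
frames run at 96×96 with 32-px patches: the counting arithmetic being verified
is independent of scene size.

Under these conditions the trained CAM segmenter reaches a held-out mean IoU
above 0.95 with sub-2° angular error, and beats the 80-px tiling baseline by a
wide IoU margin — the same ordering reported for the two approaches on real
harvest footage, where published figures are IoU ≈ 0.94 with lateral error
≈ 0.026 and angular error ≈ 4.2° for the CAM method. Synthetic textures are
cleaner than rice paddies, so desk-scale numbers are better than field numbers;
the tests assert the scaled targets (IoU ≥ 0.85, |lateral| ≤ 0.05, angular ≤ 6°,
CAM > tiling), not the field values.

## Numerical and degenerate-input choices

* Argmax ties in per-pixel classification resolve toward background (a tie
  means no class evidence dominates; background is the conservative call for a
  guidance system).
* `edge_line` canonicalizes θ into [0°, 180°), flipping ρ's sign as needed;
  horizontal lines have no bottom-row intersection and error out of the
  lateral metric explicitly.
* Contours spanning fewer than 3 rows are rejected as degenerate rather than
  fit.
* An empty mask raises a typed error (`emptyMaskError`) rather than returning
  a fabricated line.
* Max-pooling breaks ties by first occurrence (deterministic backward pass);
  inputs with odd spatial size after the required /8 divisibility cannot occur.
* The connected-component labeler is 8-connected (diagonal speckle bridges
  count as one region, matching how small misclassification clusters behave).

## Known limitations

* The backbone is texture/colour-driven by design; scenes whose classes are
  not separable by local appearance (heavy shadow, lodged crop) are outside
  the model's assumptions.
* One straight line summarizes the edge; curved edges and temporal smoothing
  across frames are out of scope, as is the homography from image to field
  coordinates that a steering controller would need.
* CAM localization is at 1/8 resolution before upsampling; very thin crop
  remnants (late in a harvest pass) fall below that resolution and below
  `min_area`, and the detector will correctly report a degenerate contour
  rather than a line.
* Inference-time benchmarking is hardware-dependent and deliberately not part
  of the evaluation surface.
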