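# cropcam

Weakly supervised segmentation of the uncut crop area in combine-harvester
front-view scenes, and detection of the uncut crop edge as a single straight
guidance line.

## The problem

A combine harvester is steered along the boundary between the still-standing
crop and the already-harvested stubble. Automating that perception from a cab
camera runs into two data problems: dense pixel labels are laborious and
genuinely ambiguous at the ragged crop boundary, and harvest footage is so
self-similar that few independent training frames exist. `cropcam` implements
a weakly supervised alternative for researchers in agricultural machine
vision: the only supervision is an image-level class label on class-pure image
patches, and pixel-level localization falls out of the classifier's own class
activation maps.

## The method

A shallow 4-layer CNN (3×3 convolutions, ReLU, 2×2 max-pooling after the
first three blocks; 256 final feature maps $f_k$ at 1/8 input resolution) is
trained to classify patches of three classes — uncut crop, harvested area,
background — with a global-average-pooling head:

* GAP score per map: $G_k = \tfrac{1}{N}\sum_{x,y} f_k(x,y)$
* class logits: $z_c = \sum_k \omega_k^c\, G_k$ (bias-free head), softmax over
  the 3 classes; MSE loss against the one-hot label, Adam (lr 1e-4, batch 64),
  early termination at the lowest validation cost.

At test time the same weights segment a whole scene:

* class activation maps: $M_c(x,y) = \sum_k \omega_k^c f_k(x,y)$
* per-pixel categorical softmax $P_c(x,y)$, bilinear upsampling, per-pixel
  argmax, and 8-connected small-component removal give the crop mask;
* the mask's contour is trimmed by 10% of its row extent top and bottom, the
  rightmost pixel per row is kept, and a ρ–θ Hough accumulator (1 px, 1°,
  near-vertical window) votes for lines whose parameters are averaged into the
  single uncut-crop-edge line.

An 80×80 image-patch-classification (IPC) baseline, a synthetic scene
generator with pixel-perfect ground truth, and the evaluation metrics
(IoU against polygon ground truth, lateral error = bottom-point offset /
image width, angular error in degrees) round out the pipeline.

## Worked example

```r
library(cropcam)

# a synthetic scene with known geometry
spec  <- scene_spec(width = 180, height = 180, horizon_row = 68,
                    edge_bottom_x = 100, edge_angle_deg = 5, seed = 42)
scene <- generate_scene(spec)
scene
#> scene -: 180 x 180, classes bg/crop/harv = 12240/11800/8360 px, edge bottom_x = 100.0, angle = 5.0 deg

# the edge detector recovers the generator's line from the ground-truth mask
detect_uncut_edge(matrix(as.integer(scene$mask == 1L), 180))
#> edge line: rho = 114.63 px, theta = 5.00 deg (5.00 deg from vertical), bottom_x = 99.42
```

The mask partitions the frame into the three classes (here 12240 sky, 11800
crop, 8360 stubble pixels); the detected line meets the bottom row at
x = 99.4 against a true 100 and recovers the 5° lean exactly — within the 1 px
/ 1° Hough quantization.

The full experiment — generate an 80-frame drifting sequence, train on the
first 60 frames, evaluate CAM segmentation against the IPC baseline on the 20
held-out frames — is one call:

```r
res <- run_pipeline(default_run_config(seed = 1), verbose = TRUE)
res$summary
```

On the held-out frames of the seed-1 run this prints mean IoU 0.970 for the
CAM segmenter with mean |lateral error| 0.0086 (fraction of image width) and
mean angular error 1.6°, against IoU 0.625 for the 80-px tile baseline — the
pixel-level CAM method beats patch-level classification by a wide margin while
using identical trained weights. `predict()` on the returned model also exposes
`type = "prob"`, `"class"`, `"features"`, `"cams"` and `"segmentation"`, and
`plot()` draws the training curves.

## Command-line use

```sh
inst/cli/cropcam generate --out scenes/ --n-frames 80 --seed 1
inst/cli/cropcam build-dataset --scenes scenes/ --out dataset/
inst/cli/cropcam train --dataset dataset/ --out model.ckpt --seed 1
inst/cli/cropcam segment --model model.ckpt --image scenes/frames/0070.png --out mask.png
inst/cli/cropcam detect-edge --mask mask.png --out edge.json
inst/cli/cropcam evaluate --scenes scenes/ --model model.ckpt --out report/
inst/cli/cropcam run --seed 1 --out artifacts/     # everything above at once
```

See `vignettes/cropcam-methods.Rmd` for the model, its assumptions, all
tunable parameters, and the design decisions behind the defaults.
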