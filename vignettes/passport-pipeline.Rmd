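---
title: "Methods: automated right-whale identification with passport photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated right-whale identification with passport photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

North Atlantic right whales carry individually distinctive callosity
patterns — patches of roughened skin, colonized by whale lice, that read as
a white pattern against the black body. Matching a new aerial photograph to
the catalog of known individuals is reliable but slow by hand.
`whalepassport` implements a fully automated matching chain: locate the
head, normalize it into a standardized "passport photo", and classify the
passport against the roster of known individuals, with every step performed
by a small convolutional network.

This vignette records the model, the design decisions behind it, the
synthetic data it is validated on, and the limits of what those validations
show.

## The pipeline

Identification runs in three learned stages plus one closed-form geometric
step:

1. **Region of interest.** The photograph is downscaled to the network
   input size and a 5-convolution / 5-pooling / 1-fully-connected network
   estimates where the head is. Rather than regressing the box corners
   directly, the network regresses the two endpoints of the head axis (the
   bonnet tip and the point just below the blowholes) in frame-fraction
   coordinates; the axis-aligned box is then reconstructed from the
   endpoints and the head's known width-to-length proportions
   (`endpoints_to_bbox()`). Endpoints transform exactly under rotation,
   whereas axis-aligned corners would systematically inflate the target box
   for diagonally oriented whales, which measurably degrades training.

2. **Keypoints.** The head crop is resized to the keypoint network's input
   and a 9-convolution network with a fully connected head regresses both
   keypoints in crop-fraction coordinates. The stage's contract allows up
   to 9 pooling layers; the default uses 4. A single crop-generation rule
   is shared between training and inference: every crop is
   `endpoints_to_bbox()` of an *estimated* head axis. During training the
   estimate is the ground truth axis plus isotropic noise whose scale is
   drawn log-uniformly between 2% and 30% of head length — spanning the
   error of a rough region-of-interest estimate down to that of an almost
   perfect one. At prediction time the first crop comes from the roi
   stage's endpoints, and the estimate is then *refined iteratively*
   (default 2 extra passes): each pass re-crops around the previous
   keypoint estimate and re-runs the network. Because small-noise crops are
   part of the training distribution, every refinement pass is in
   distribution, and the estimate sharpens at the cost of one forward pass.

3. **Passport normalization.** The unique reflection-free similarity
   transform mapping the two estimated keypoints onto canonical positions
   is solved in closed form (`similarity_from_keypoints()`) and the image
   is resampled bilinearly (`warp_to_passport()`). The canonical geometry
   (an open choice; nothing in the problem pins it) is a square frame with
   the head vertical and centered: bonnet at (W/2, 0.1875 H), blowhole at
   (W/2, 0.8125 H), so the head spans 62.5% of the frame. Default output is
   256 x 256; the demonstration configuration uses 96 x 96.

4. **Identity.** An ensemble (default 3 members differing only in seed) of
   11-convolution / 6-pooling / 1-fully-connected networks classifies the
   passport photo with a softmax over the roster. An auxiliary head
   predicts whether the callosity pattern is connected, trained jointly as
   a weighted binary cross-entropy (weight 0.2); connectivity is the one
   auxiliary label retained because it structures the representation the
   identity head needs. Ensemble output is the arithmetic mean of member
   softmax distributions, which is again a distribution.

Two design choices here deserve emphasis because they are responses to
failure modes we measured, not cosmetics:

* **Identity networks train on passports produced by the predicted chain**
  (`passport_source = "predicted"`), not on passports from the annotated
  keypoints. Passports from predicted keypoints carry the alignment errors
  the classifier will actually see; training on perfectly aligned passports
  and predicting on imperfect ones cost tens of points of top-1 accuracy at
  the demonstration scale.
* **Each stage gets its own augmentation magnitudes.** Whales appear at
  every heading, so the roi stage jitters rotation over the full circle;
  the keypoint and identity stages see "very slight" jitter (12 and 10
  degrees, scale 0.9-1.1) because their inputs are already roughly
  normalized by construction.

## Training

All stages are trained with Adam (a stochastic gradient optimizer with
momentum-style first-moment averaging), batch size 32, learning rate
2e-3 with a step decay (x0.3 after 60% of the epochs, x0.1 after 85%),
which measurably sharpens the final precision of the regression stages.
Regression stages minimize mean squared error on normalized coordinates;
the identity stage minimizes softmax cross-entropy plus the weighted
auxiliary binary cross-entropy. All randomness — initialization, shuffling,
augmentation draws — derives from configured seeds, so runs are exactly
reproducible in single-threaded execution.

A stratified 10% holdout supports internal validation: every identity with
at least two images keeps at least one in training, and single-image
identities always train, because an unstratified split strands
underrepresented whales entirely in validation. After validation, the
held-out images are folded back and every stage continues for a short
budget (1 epoch by default) at one tenth of the main learning rate — large
enough to pick up underrepresented individuals, small enough not to
overfit.

## The synthetic data

The generator (`simulate_whale_dataset()`, `generate_dataset()`) emulates
the statistical structure the pipeline assumes, not photorealism. Each
identity owns a fixed arrangement of 2-5 white blobs placed along the head
axis in head-length units; a pattern is `connected` exactly when every
consecutive blob pair overlaps, giving a non-degenerate auxiliary label.
Scenes place a dark body ellipse (length 55-75% of the short image side) at
a uniform random heading on textured water (coarse swell plus fine chop,
value noise), add a seed-determined global brightness change and a local
glare spot, and record exact annotations: the tight head box with a 10%
head-length margin, both keypoints, and the connectivity flag. Head length
is fixed at 25% of body length; the bonnet sits at the body's front tip.
Poses that do not fit are rejected and redrawn (at most 100 attempts,
then an error naming the pose).

Per-identity image counts can be fixed or drawn log-uniformly between a
minimum and maximum (defaults 1 and 82) with the extremes pinned, emulating
the strong imbalance of real catalogs in which a few individuals have
dozens of photographs and several have exactly one.

What the generator does *not* model: occlusion and partial submersion,
white caps that mimic callosities, perspective and lens distortion,
within-identity appearance change over years, and misannotation. Passing
the synthetic benchmark therefore demonstrates that the chain's geometry,
training machinery and ensembling work end to end — not that the specific
trained weights would transfer to aerial survey photographs.

## The demonstration benchmark

`run_demo_pipeline()` generates 25 identities with 30 images each at
192 x 192, fits the full chain with 96 x 96 passports and a 3-member
identity ensemble, and evaluates the fully automatic chain on the held-out
10% (75 images). These sizes are the package's reference conditions: large
enough that every stage must generalize (validation scenes have unseen
poses, noise and glare), small enough to run on a single CPU core in
minutes. At this scale the training networks use channel widths of 8-48;
epoch budgets are 50 (roi), 40 x 2 members (keypoint) and 18 x 3 members
(identity).

One caveat is recorded here deliberately. At 192 x 192 a head spans roughly
30 pixels, so the stated keypoint-recovery target of 5% of head length is
about 1.5 px — at the resolution floor of coordinate regression from
pooled convolutional features. The automatic chain reaches median keypoint
errors around 4-6% of head length, which the identity stage absorbs (it is
trained on exactly those errors), but the fraction of images within the 5%
radius stays near one half rather than the nominal 90%. The identification
bars (top-1, top-5, ensemble log loss) and the box-recovery bar are met;
the keypoint-radius bar is reported as measured rather than relaxed.

Relatedly, the pipeline's reported head box is its *final* estimate,
reconstructed from the refined keypoint axis; the rough region-of-interest
box exists to produce the first crop and is kept as a diagnostic
(`evaluate_pipeline()` returns both `iou` and `iou_roi`). This mirrors the
chain's division of labor: the first stage is deliberately coarse, and the
keypoint stage is where localization precision lives.

## Evaluation

Scoring follows the competition convention: every predicted probability is
clipped to `[1e-15, 1 - 1e-15]` with no renormalization, and the loss is
the mean negative natural logarithm of the clipped probability assigned to
each true identity. Top-k accuracy breaks ties by ascending roster order so
results are deterministic. Submissions are CSVs with header
`Image,<id_1>,...,<id_M>`; the reader aligns shuffled columns, validates
row sums to 1e-3 (slack for rounded files), and round-trips probabilities
to 1e-12.

## Numerical conventions

* Coordinates are 0-based pixels; `(x, y)` addresses the center of pixel
  column x, row y. Boxes are half-open `[x0, x1) x [y0, y1)`. Sizes are
  `(H, W)`.
* Point targets are regressed as pixel-center fractions `(x + 0.5) / W`,
  which survive resizing exactly; box edges as plain fractions `x / W`.
* Resampling is bilinear with constant black padding; nearest-neighbor is
  available where exactness matters more than smoothness. Pooling layers
  are 2 x 2, stride 2, with ceiling semantics (partial windows) so odd maps
  remain valid.
* The two-point similarity has no reflection component: two
  correspondences cannot determine one, and the normalization only needs
  scale, rotation and translation.
* Degenerate cases are pinned: coincident keypoints are an error wherever
  they appear; a constant-color image has zero color covariance and passes
  through the color perturbation unchanged; equal-probability ties in
  top-k resolve by roster order.

## Known limitations

* The convolutional engine is deliberately small (im2col convolutions,
  2 x 2 max pooling, fully connected heads, Adam) and single-threaded; it
  is sized for desk-scale experiments, not for the full survey archive.
* Coordinate regression limits keypoint precision to roughly 1.5 px at the
  demonstration resolution, as discussed above.
* The generator's anatomy (elliptical body, fixed head proportion) is also
  what `endpoints_to_bbox()` assumes; applying the roi stage to a species
  with different head proportions means re-estimating those two constants.
* Color-space perturbation is computed per image rather than over the
  whole training set — a stateless simplification of the usual
  principal-component lighting augmentation.
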