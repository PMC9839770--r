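---
title: "Centroid-crop self-training for lesion segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centroid-crop self-training for lesion segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dental caries appear in bitewing radiographs as small dark lesions — on the
order of 10 × 10 pixels inside 300 × 300 frames, i.e. roughly 0.1 % of the
pixels.  Two obstacles make supervised segmentation hard in this setting:
pixel-level annotations are expensive to obtain from clinical experts, and
the extreme foreground/background imbalance lets a pixel-wise classifier
reach very low loss by predicting background everywhere.

`ccseg` implements a teacher–student self-training pipeline built around
*centroid cropping-based sampling* (CCS) that addresses both.  A teacher
model \(M_T\) is trained on a small labelled set \(D_L = \{(x_i^l, y_i^l)\}\);
its thresholded predictions on unlabelled images \(D_U = \{x_j^u\}\) become
pseudo labels \(y_j^p\), and a student \(M_S\) is trained on the pseudo pairs
\(D_P = \{(x_j^u, y_j^p)\}\) together with the real labelled pairs.  Both
models minimise mean per-pixel binary cross-entropy

\[
\mathcal{L}(y, \hat y) = -\frac{1}{|\Omega|}\sum_{p \in \Omega}
  \big[ y_p \log \hat y_p + (1-y_p)\log(1-\hat y_p) \big],
\]

with predictions clipped to \([10^{-7}, 1-10^{-7}]\).

## Centroid cropping-based sampling

CCS locates the 8-connected foreground components of a (real or pseudo)
mask, and cuts a fixed-size square window centred on each component
centroid out of both image and mask:

* the window side defaults to 32 px (10 px reproduces the size of the
  average lesion itself; 32 keeps enough context for a convolutional model
  whose receptive field spans several pooling stages while preserving most
  of the rebalancing benefit);
* the top-left corner is `round(centroid) - floor(side/2)` per axis, then
  shifted — never shrunk, never padded — by the minimum amount that puts
  the window fully inside the frame, so patches contain only genuine image
  content;
* a component whose bounding box exceeds the window is covered by enlarging
  the side to the box plus a 2-pixel margin, so no lesion is ever truncated;
* no minimum-area filter is applied by default (`min_area = 1`).

On the default synthetic statistics (below), crops carry a foreground
fraction roughly 30 times that of the full frames; this removal of the
class imbalance is what lets a plain-BCE student learn the lesion class
reliably.  Images whose pseudo mask is empty produce no crops; they are
flagged and skipped (their contribution would be pure background, which the
crops of other images already provide in abundance).

## Augmentation

Each cropped pair is expanded into exactly five by a fixed, deterministic
transform list: identity, horizontal flip, vertical flip, rotation and
x-shear.  Flips are index permutations (exact involutions, exactly
area-preserving).  Rotation (default 15°) and shear (default 0.2) act about
the patch centre with the output shape preserved; the image is resampled
bilinearly, the mask by nearest neighbour and re-binarised at 0.5, and
out-of-support pixels are filled with 0.  Fixed magnitudes rather than
per-item random draws make the 5× expansion exactly reproducible; the
magnitudes themselves are mild enough that a lesion near the patch centre
stays in the patch.

## The pipeline

`run_self_training()` orchestrates one experiment:

1. **Split** (`split_dataset`): `round(0.1 N)` images are held out as the
   test set; `n_teacher` of the rest (default 20) form the labelled teacher
   set; the remainder becomes the pool, whose masks are hidden from every
   training path and retained only to audit pseudo-label quality.
2. **Teacher**: trained on the labelled full frames; in CCS mode
   additionally on their centroid crops, 5-way augmented (the
   `augment_teacher` flag).  Training the teacher on fg-rich crops as well
   as frames counters the imbalance-driven under-segmentation that
   otherwise makes pseudo masks systematically too small.
3. **Pseudo labels**: teacher probabilities thresholded at 0.5 (exposed as
   `pseudo_threshold`).
4. **Student**: in standard mode, trained on full-frame pseudo pairs plus
   the real labelled frames; in CCS mode, on the 5-way augmented centroid
   crops of the pseudo pairs (and of the real pairs).  By default the CCS
   student sees crops only; `student_full_frames = TRUE` adds the frames.
5. **Evaluation**: both models run full-frame inference on the held-out
   test images (the backbone is fully convolutional, so crop-trained
   students apply directly to frames); metrics are computed against real
   ground truth only, never pseudo labels.

Test-set isolation is asserted from the logged id manifests on every run.

## Metrics

From per-image confusion counts (foreground = positive):

* mean pixel accuracy `mPA` — the mean over classes of per-class recall
  \(n_{jj}/t_j\) with \(t_j\) the ground-truth pixel count of class *j*;
  classes absent from the truth are excluded from the mean.  Interpreting
  \(t_j\) as the *prediction* total would make the quantity unbounded, so
  the recall form is used;
* `IoU` per class — \(TP/(TP+FP+FN)\), the set form
  \(|X \cap Y|/|X \cup Y|\); `mIoU` averages foreground and background IoU,
  which is how two-class segmentation tables are usually reported
  (accuracy near 1 with mIoU near 0.5 is the signature of 2-class
  averaging); the foreground-only IoU is always reported alongside;
* `Dice` — \(2TP/(2TP+FP+FN) = 2\,\mathrm{IoU}/(1+\mathrm{IoU})\).

When both masks are empty for a class the score is defined as 1 (an empty
prediction of an empty truth is perfect agreement; this also keeps 0/0 out
of the aggregation).  Micro (pool counts, then score) and per-image
(score, then average) aggregations are both computed and labelled, since
published tables rarely state which was used.

## The backbone

No deep-learning framework is assumed: the built-in backbone is a small
fully convolutional encoder–decoder written with hand-derived gradients
over C++ kernels — three 3×3-conv + ReLU + 2×2-max-pool stages (8/16/32
channels), a 3×3 bottleneck, nearest-neighbour upsampling with skip
concatenations, 3×3 decoder convs at the two coarse levels, a 1×1 fusion at
full resolution, and a sigmoid head (≈27 k parameters).  The 1×1 fusion at
the most expensive resolution keeps one CPU core sufficient; spatial
context is supplied by the coarser levels, full-resolution detail by the
first-stage skip.  Inputs are zero-padded internally to multiples of 8 and
cropped back, so any frame size works.  The forward/backward pass exists
twice — a composition of small R layer functions, and a fused C++ pass —
and the test suite requires the two to agree to machine precision, with
finite-difference checks on the analytic gradients.

Any other model can stand in for the built-in backbone by implementing the
`predict_probs()` / `model_fit()` generics (and `save_checkpoint()` for
persistence); named large-scale architectures are deliberately out of the
package's scope.

## Training

`train_config()` defaults follow the experimental setup the pipeline
emulates: batch size 8, fixed learning rate 10⁻³, at most 100 epochs,
early stopping when the validation loss (10 % of the training pairs) fails
to improve by more than 10⁻⁴ for 5 consecutive epochs; the best-validation
checkpoint is kept.  The update rule is Adam; the reference setup names
only a fixed learning rate, and plain SGD at 10⁻³ is far too slow for a
from-scratch CPU model, so the standard adaptive variant of stochastic
gradient descent is used and recorded in every run report.  Batches never
mix item shapes (full frames and crops are grouped separately).  All
randomness — weight initialisation, validation split, shuffling — derives
from explicit seeds, and repeated runs are bit-identical.

## Synthetic data

`generate_radiograph()` emulates the statistics that matter for the
method, not radiographic physics: a dark background (≈0.15), a row of
bright tooth-like ellipses (≈0.7), and 1–3 dark lesion blobs per image
placed on tooth boundaries.  Each lesion is a thresholded anisotropic
Gaussian bump with jittered edges; its nominal side is drawn from
Normal(10, 2) px, clipped to [2, min(H, W)/4], and its pixels are darkened
by `lesion_contrast` (default 0.3) scaled by the bump profile, so the mask
support is exactly the set of modified pixels.  Lesions are separated by at
least 2 px (rejection sampling, ≤100 attempts), so the number of
8-connected mask components equals the number of placed lesions.  I.i.d.
Gaussian noise (sd 0.03) is added and the image clipped to [0, 1].  Every
draw is a pure function of `(seed, draw_index)`.

At the default 300 × 300 scale with side-10 lesions the foreground fraction
lands in the 0.1 % regime that motivates CCS.  What the generator does
*not* reproduce: overlapping crowns, variable exposure, annotation noise,
lesion-grade continua, or anatomy beyond "bright blobs in a row" — passing
tests on this data demonstrate the pipeline's mechanics and the direction
of the CCS effect, not clinical performance.

## The benchmark study

`run_benchmark_study()` is the package's end-to-end experiment at a scale
one CPU core handles in a few minutes per seed: 120 synthetic frames of
96 × 96 px with side-8 lesions (four teeth per row — the generator's
appearance parameters scaled to the smaller frame), split 20 teacher /
60 pseudo-labelled pool / 12 test, three independent run seeds, and three
regimes per seed — CCS self-training, standard self-training, and a
supervised baseline trained on the teacher subset only.  The quantities it
reports (student foreground IoU and mIoU per regime, baseline IoU,
pseudo-label fidelity as mean per-image foreground IoU against hidden pool
truth) are exactly what `scripts/acceptance.R` writes and what the
acceptance tests assert on: the CCS student should reach foreground IoU
≥ 0.5, beat the supervised baseline, and beat standard self-training on
mIoU, and the teacher's pseudo labels should reach fidelity ≥ 0.4.

On this synthetic benchmark standard self-training frequently collapses to
all-background predictions — the imbalance failure mode CCS exists to
remove — so the CCS-vs-standard margin here is much larger than the few
percentage points reported on real radiographs.

## Numerical choices and edge cases

* Pixel-centre containment with even-odd fill (plus explicit boundary
  inclusion) defines polygon rasterisation; a LabelMe vertex (x, y) maps to
  the centre of the 0-based pixel (row y, col x).
* Mask image files binarise at > 127 on the 8-bit scale, robust to
  antialiased exports; write-then-read is the identity.
* Window placement rounds half away from zero (`floor(x + 0.5)`), avoiding
  platform-dependent banker's rounding.
* Max-pool ties keep the first candidate in (down, right, diagonal) order;
  the C++ and R paths share this order, which the equivalence test pins.
* Early stopping compares against the best seen loss with min-delta 10⁻⁴;
  training aborts with the epoch index if the loss goes non-finite.
* Empty pseudo-label sets after CCS raise an error pointing at teacher
  quality rather than training a student on nothing.

## Known limitations

* The built-in backbone is deliberately tiny; absolute numbers on real
  radiographs would require a modern pretrained segmentation network
  plugged in through the model contract.
* Single-round self-training only: no iterative re-labelling, no soft
  pseudo-labels, no confidence weighting.
* Binary masks only (lesion vs background), one label class per mask.
* The LabelMe reader covers the polygon dialect (shapes with ≥3 points);
  rectangle/circle shape types are not interpreted.
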