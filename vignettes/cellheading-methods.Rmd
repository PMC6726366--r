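---
title: "Predicting the direction of cell migration from single image patches: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the direction of cell migration from single image patches: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

Migrating cells are polarized: actin-driven protrusions extend at the
front and set the direction of travel, while the trailing edge contracts
behind. Because this polarity is visible in a single phase-contrast
snapshot, the *future* direction of movement is partly encoded in the
*current* shape. `cellheading` implements a complete workflow that
exploits this: it annotates tracked cells with a four-quadrant moving
direction, trains a convolutional network to predict that direction from
one image patch, and attributes the prediction back to pixels so the
morphological cues the network uses (protrusion, trailing edge, the
phase-contrast halo) can be inspected. A seeded synthetic-movie
generator, in which morphology determines future heading by
construction, lets the whole pipeline be exercised and validated without
microscope data.

## Direction annotation

For a tracked cell at anchor frame $t_0$, the net displacement
$\Delta r(t) = \sqrt{\Delta x^2 + \Delta y^2}$ is scanned forward on an
evaluation grid (15-minute spacing by default, regardless of the
acquisition interval) until it first *strictly* exceeds one cell
diameter, 18 µm — the average diameter of NIH/3T3 fibroblasts. The label
is the quadrant of the displacement at that crossing, in image
coordinates (y grows downward):

| label | code | rule |
|---|---|---|
| upper right | 0 | $\Delta x \ge 0,\ \Delta y \le 0$ |
| upper left  | 1 | $\Delta x < 0,\ \Delta y \le 0$ |
| lower left  | 2 | $\Delta x < 0,\ \Delta y > 0$ |
| lower right | 3 | $\Delta x \ge 0,\ \Delta y > 0$ |

Cells that never cross before their track ends are excluded. Two
motility statistics are computed over the same window: average speed
$v = \sum \Delta d / \Delta t$ (path length on the evaluation grid over
elapsed time) and directionality $k = \Delta r / \sum \Delta d$, which
is 1 for straight persistent motion.

Numerical choices worth stating: the threshold comparison is strict
(`>`), so a displacement of exactly 18 µm continues the scan; the
evaluation grid is anchored at $t_0$ and a missing grid frame ends the
scan (a lost cell is treated as track end); every track point can serve
as an anchor, so one cell yields many (anchor, label) samples.

## Patch preparation

Patches are square crops centered on the tracked coordinate,
edge-replicated where the crop leaves the frame (so border anchors stay
usable), and resized by bilinear interpolation with half-pixel sample
centers — under an exact 2:1 reduction this averages 2×2 blocks and
preserves the patch mean. Each patch is normalized by subtracting its
minimum and dividing by the maximum of the result, mapping it to
$[0, 1]$; a constant crop maps to all zeros rather than dividing by
zero.

Training-set augmentation applies the six planar isometries (identity,
horizontal and vertical reflection, rotations by 90°, 180°, 270°).
Geometry forces the label to transform with the patch — the 90°-rotated
image of a right-moving cell shows an up-moving cell — so labels are
remapped by the same isometry (rotations advance the quadrant cycle,
reflections swap the mirrored pair). A `fixed_labels` switch reproduces
the literal alternative of keeping labels unchanged. Augmentation is
applied to training folds only, never to validation or test data.

The train/validation/test split is stratified by label with per-class
rounding `n_val = ceiling(0.2 n)`, `n_test = round(0.2 n)`, remainder to
training — the rounding that reproduces the per-class counts this
workflow is normally run with. Splitting is at the patch level by
default; patches of one cell may land in different splits, which mirrors
the reference counts but admits within-cell leakage — for leakage-free
evaluation the assembly step can be restricted to one anchor per cell,
as the synthetic pipeline does.

## The network

The classifier is a 14-layer CNN: eight stride-1 convolutions (5×5×8,
5×5×32, 3×3×40, 5×5×32, 5×5×48, 5×5×64, 5×5×64, 5×5×72) with a 2×2
stride-2 max-pooling after each pair, then fully connected layers of
1000 (ReLU, dropout 0.3) and 4 units, softmaxed into the distribution
over directions. Convolutions use "same" zero padding: it is the only
convention under which the four poolings reduce the input cleanly
(128 → 8, or 64 → 4 at the reduced scale), whereas unpadded
convolutions would degenerate before the final pooling. With a 128-px
input the first fully connected layer sees 8·8·72 = 4608 features and
the network has 4,996,284 trainable parameters (1,540,284 at 64 px);
`model_summary()` reports the per-layer breakdown.

Weights are initialized He-normal — $\mathcal{N}(0, \sqrt{2/\mathrm{fan_in}})$
with fan-in $k^2 c_\mathrm{in}$ for convolutions — and biases at zero.
Training is plain SGD with momentum (base learning rate 0.021, momentum
0.5) on class-weighted softmax cross-entropy for 50 epochs (15 at the
reduced synthetic scale) with stratified batches of 46 images: each
batch's class proportions match the training set's within one sample.
The class weight $w_k = \sum_j N_j / (n N_k)$ down-weights
over-represented directions; the batch loss is normalized by the summed
weights of its samples, which keeps the effective learning rate stable
under reweighting and makes the weighted loss coincide exactly with the
unweighted loss on balanced data. Dropout (rate 0.3, inverted scaling)
acts on the first fully connected layer only.

Cross-validation is stratified into 4 folds; per fold the best-epoch
checkpoint is tracked separately for validation ACA (overall correct
rate) and MCA (unweighted mean of per-class rates). The deployed model
is the checkpoint with the highest validation MCA across folds — MCA is
the criterion robust to imbalance — with ties resolved toward the
earlier epoch and lower fold index; selection by ACA is available via
`select_by`. Prediction ties (equal logits) resolve to the lowest class
index.

The numerical engine (im2col convolution, pooling, backpropagation) is
implemented in the package's C++ layer. The training loop runs in
single precision, which is standard for CNN optimization; forward
evaluation, gradient checks and attribution run in double precision so
that the conservation and gradient identities below hold to $10^{-6}$.
Analytic gradients are verified against central differences on a
reduced architecture in the test suite. Training aborts with a
diagnostic if the loss turns non-finite.

## Attribution

Three complementary methods explain a prediction:

**Guided backpropagation (GBP)** backpropagates a single post-ReLU
activation — typically the spatial maximum of a feature map in the last
convolutional layer, ties resolved to the first position in row-major
order — down to pixels, zeroing the backward signal at every ReLU where
the forward activation was non-positive *or* the incoming signal is
negative. With every gate open (positive weights and inputs) GBP equals
the plain gradient, which the tests exploit as an oracle. A target with
zero activation yields an all-zero map.

**Deep Taylor decomposition (DTD)** redistributes the pre-softmax score
of the chosen class (the predicted class by default) down the network:
the $z^+$ rule through hidden convolutional and fully connected layers
(positive weight parts only, biases excluded), winner-take-all routing
through max-pooling, identity through ReLU, and the $z^B$ rule with box
bounds $[0, 1]$ at the input layer, matching the patch normalization
range. This yields non-negative per-pixel relevances that, with zero
biases, sum to the output score; the implementation guards zero
denominators (that unit's relevance is dropped) and clips the
$\sim 10^{-15}$ negative rounding residues of the $z^B$ subtraction. A
non-positive output score carries no positive evidence to decompose: the
map is defined as all zeros and a warning is raised.

**Occlusion** slides a 7×7 mask (edge-cropped at borders) over every
pixel, fills it with the patch mean (zero-fill available), and records
the negated class score; the pre-softmax logit is used for linearity,
with a softmax option. The map is min–max scaled to integers in
$[0, 255]$; a flat response (e.g. a constant predictor) maps to all
zeros. The occluded class defaults to the patch's predicted class and
can be set to the true label.

On synthetic data the three methods are checked against each other: DTD
relevance concentrates on the cell rather than the background of
correctly predicted patches, and the top-decile pixel sets of any two
methods overlap substantially.

## The synthetic generator

Each simulated cell performs a persistent random walk: headings follow a
von Mises turning kernel (concentration $\kappa$, sampled by the
Best–Fisher rejection scheme; $\kappa = 0$ is an uncorrelated walk) and
step lengths are truncated-normal speeds times the frame interval.
Reflecting walls keep cells in frame without globally biasing the
direction classes. Cells are rendered as star-convex silhouettes whose
radius varies with the angle to the heading: a dark body (intensity
0.25) on mid-gray background (0.5), a broad protrusion lobe ahead
(Gaussian angular profile), a narrow trailing edge behind (12° width),
and a bright halo ring just outside the silhouette — a qualitative mimic
of phase contrast, where the halo arises from cell thickness. Overlaps
overdraw in cell-id order. Gaussian intensity noise is added and values
clipped to $[0, 1]$. Identical (config, seed) pairs reproduce movies and
tracks bit for bit.

The coupling that makes the prediction task solvable is explicit: the
rendered protrusion axis *is* the direction of the next displacement
(optional jitter available). Defaults, chosen once as a plausible
fast-moving fibroblast-like regime: body radius 9 µm (the 18-µm
diameter), protrusion 11 µm long with 40° half-width, tail 13 µm, speed
1.5 ± 0.3 µm/min — so the typical 15-min step (22.5 µm) crosses the
18-µm annotation threshold within one evaluation interval and the
annotated label is the quadrant of a single morphology-aligned step —
and κ = 6, giving the strongly persistent paths (directionality near
0.9) of polarized cells. The 1280-px (832-µm) default frame holds 200
cells at about 450 cells/mm², a subconfluent density at which patches
usually show one whole cell; at substantially smaller frames the
permanent overlaps destroy the morphology signal the generator is
supposed to provide, and the rendering's overdraw assumption breaks
down.

What the generator does *not* emulate: textured cytoplasm and nuclei,
cell–cell adhesion and collision dynamics, division and death, shape
fluctuations decoupled from motion, illumination gradients, and focus
drift. Passing the synthetic recovery test therefore shows that the
pipeline is implemented correctly end to end — annotation, patches,
training, evaluation — and that the network can read a morphology code
of realistic geometry from realistically noisy images; it does not show
that real cells of a given type are equally predictable.

## Problem sizes and reproducibility

The synthetic study conditions are 200 cells over 40 frames at 15-minute
intervals (seed 1). For routine validation the pipeline runs at a
reduced scale chosen once: one annotated anchor per cell (200 patches —
comparable to a manually tracked dataset, and leakage-free across
splits), 96-px crops resized to 64-px patches, and 15 epochs per
cross-validation fold. At this scale the held-out test MCA lands well
above the 25% chance level (≥ 80%; the suite's end-to-end test asserts
exactly that), and the full run — simulation, annotation, patching,
4-fold training, evaluation — completes in roughly a quarter of an hour
on one CPU core. `scripts/acceptance.R` re-runs these computations from
scratch under a caller-supplied seed and writes the headline numbers as
JSON.

## Known limitations

- The synthetic morphology code is a single oriented lobe; real
  protrusion dynamics (ruffling, competing lamellipodia) are richer, and
  real datasets show cell-type-specific shapes the generator does not
  model.
- Patch-level splitting mirrors the reference workflow but allows
  within-cell correlation between splits when several anchors per cell
  are kept; use one anchor per cell (the default of the synthetic
  pipeline) or cell-level assembly for strict independence.
- The annotation rule quantizes direction to four quadrants;
  displacements near a quadrant boundary make neighboring-class
  confusions structurally likely, which is visible in the off-diagonal
  structure of the confusion matrices.
- DTD is defined here for ReLU networks with box-constrained inputs and
  positive output scores; other architectures would need different
  propagation rules.
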