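---
title: "Methods: scribble-trained pixel classification and its benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scribble-trained pixel classification and its benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scribbleseg)
```

This vignette documents the model behind `scribbleseg`, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
design decisions taken where the design was genuinely open. It states no
empirical claim that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The classification model

A segmentation here is per-pixel classification: features $\phi(p) \in
\mathbb{R}^F$ from a deterministic extractor, a tree-ensemble classifier
fitted on the feature vectors of annotated pixels only, and an
$\arg\max$ over class probabilities everywhere else. Ties at the argmax go to
the **lowest class id**, so label maps are reproducible bit for bit.

Two classifier families are built in (the environment ships no R tree
learner, so both are implemented in C++ inside the package):

* **Gradient-boosted trees** (default): multiclass softmax boosting,
  one depth-4 regression tree per class per round (40 rounds, shrinkage
  0.2), Newton leaf values $\sum r_i / \sum h_i$ with hessians
  $\frac{K-1}{K} p(1-p)$ clipped below at $10^{-12}$.
* **Random forest**: bagged CART with gini splits,
  $\lfloor\sqrt{F}\rfloor$ features per split, 100 trees of depth ≤ 12,
  probability averaging over leaf class frequencies.

Split search is exact (sort + scan); ties between candidate splits resolve
to the first candidate in (feature, threshold) scan order, and all
randomness comes from one `std::mt19937` seeded by the user-facing `seed`.
These two choices make training deterministic given the seed, which the
save/load round-trip tests rely on.

## 2. Feature extractors

### Filter bank

Per input channel and per scale $\sigma \in \{0.3, 0.7, 1.0, 1.6, 3.5, 5.0,
10.0\}$ (defaults; any positive vector accepted), eight channels in a fixed
documented order: Gaussian, Laplacian of Gaussian, Gaussian gradient
magnitude, difference of Gaussians, structure-tensor eigenvalues
(descending), Hessian-of-Gaussian eigenvalues (descending); plus one raw
intensity channel, i.e. $8 |\Sigma| + 1$ channels per input channel.

Kernel conventions (the test oracle re-derives these independently and
checks equality to $10^{-6}$ by dense convolution):

* sampled Gaussians truncated at radius $\lceil 4\sigma \rceil$ (minimum 1),
  order-0 kernels normalized to sum 1, order-1 kernels antisymmetric
  (sum 0 exactly), order-2 kernels mean-corrected to sum 0 so all
  derivative filters vanish identically on constant images;
* boundary handling is symmetric reflection including the edge pixel,
  everywhere — in full-image extraction, in annotation crops and in tiles,
  which is what makes the crop/tiling exactness guarantees possible.

Two parameter choices deviate from common conventions, deliberately:

* **Difference of Gaussians** is $G_{0.66\sigma} - G_{\sigma}$ (the
  ilastik-style inner scale), not $G_{\sigma} - G_{1.6\sigma}$: the larger
  second scale would need a kernel of radius $\lceil 6.4\sigma \rceil$ and
  silently break the declared context margin (below).
* **Structure tensor** uses derivative *and* integration scale $\sigma/2$.
  The more usual (integration $\sigma$, derivative $\sigma/2$) pair makes
  the two-pass chain support $\lceil 2\sigma \rceil + \lceil 4\sigma
  \rceil$, again exceeding the declared margin; with both at $\sigma/2$ the
  chain fits in $2\lceil 2\sigma \rceil$ and the margin stays the familiar
  $4\sigma$ rule. Exactness of crops and tiles was judged more valuable than
  matching vigra's scale pairing.

### Context margin

`context_margin(spec)` returns the halo width $m$ such that features
computed on any crop padded by $\ge m$ equal full-image features exactly:
$\max(\lceil 4\sigma \rceil, 2\lceil 2\sigma \rceil)$ over the filter bank's
scales (40 px for the default set), $\lceil 4\sigma \rceil$ for the Gaussian
baseline (12 px at $\sigma = 3$) and the context-statistics extractor,
(receptive-field radius) × (max pyramid scale) for convolutional pyramids.
Patch-embedding extractors are flagged `whole_image_context`; for them the
margin is undefined and tiling/cropping is refused unless explicitly
overridden.

### Gaussian baseline

Raw intensity plus one $\sigma = 3$ smoothed channel per input channel —
the weakest sensible extractor, used as the control arm in benchmarks.

### Convolutional featurized pyramid

The input is bilinearly downscaled by each factor in `scales` ⊆ {1, 2, 4, 8},
run through a backbone satisfying a minimal provider contract (`id`,
`n_in`, `layer_channels`, `layer_downsample`, `min_size`,
`receptive_radius`, `forward()`), and all selected layer outputs are
bilinearly upscaled to the original resolution and concatenated. The package
ships no weights: `toy_cnn_backbone()` builds seeded randomly initialized
conv/ReLU stacks (optionally tanh activations, max- or average-pooling at a
configurable subset of stages) so that every architectural code path is
exercised offline. Pretrained VGG16-class backbones plug in through the same
contract. Default pyramid: scales {1, 2}, all layers of the toy three-stage
backbone.

### Patch embeddings

`extract_vit_patch()` resizes each side to the *nearest* positive multiple
of the patch size (bilinear), cuts non-overlapping patches and embeds each
through the backbone (toy stand-ins: 14 px/384-d "small" and 16 px/1024-d
"large" geometry, random projection + tanh). `upsample_patch_features()`
maps pixel centres through the resize before patch lookup, so the
nearest-neighbour upsampling is exact back-mapping: each pixel carries its
covering patch's embedding unchanged (piecewise-constant semantics);
bilinear interpolation of the patch grid is available but not default.

### Large-window context statistics

`extractor_context_mean(sigmas = c(16, 48))` computes, per channel and
scale, the Gaussian-window mean and standard deviation
($\sqrt{\smash{G_\sigma(I^2) - (G_\sigma I)^2}}$). It is registered through
the same plugin registry a third-party extractor would use. Why it exists —
and why the randomly initialized CNN is *not* the reference context
extractor — is explained in §6.

### Fusion and volumes

`combine_features()` concatenates any list of same-shape scale-1 feature
maps in order; a combined spec's margin is the max of its children's, and it
inherits `whole_image_context` if any child has it.
`extractor_multiprojection(base)` runs a 2D extractor slice-wise along the
xy, xz and yz orientations of a z-stack and concatenates the three blocks
($3F$ channels), exactly voxel-aligned; anisotropic voxels are *not*
resampled first (documented caveat — extract on the raw grid).

## 3. Training and prediction mechanics

`sample_training_set()` touches only planes containing annotations; for
local extractors it extracts features on the bounding box of the annotated
pixels padded by the context margin (clipped to the image; reflection then
coincides with full-image reflection), so the training matrix is
*identical* to full-image extraction — an invariant tested to bit equality.
Rows are ordered by ascending (plane, y, x). Whole-image-context extractors
fall back to full planes, volumetric ones to the full volume.

Prediction is streamed per plane (`predict_stack()` also accepts a
`function(p)` plane source for larger-than-memory data), or per tile:
`plan_tiles()` builds a deterministic row-major partition into core
rectangles (last row/column may be smaller) with padded rectangles extending
each core by the margin, and `predict_tiled()` stitches core crops. With
margin ≥ context margin the result is bit-identical to untiled prediction,
for any tile size and worker count; tiles are independent work items and the
merge is order-independent. The fast path for expensive extractors
(`predict_with_downscale()`, factor 2 by default) downscales bilinearly
before features, upscales the label map by nearest neighbour (preserving
label integrality) and applies a majority filter (default radius 1, i.e.
3×3; ties keep the centre label, making uniform maps and straight two-block
boundaries fixed points).

Class imbalance is not reweighted; normalization statistics are percentile
rescaling (defaults 1/99) per plane or per stack, always **per channel** —
the pooled-across-channels alternative would let a bright channel dominate
multiplexed stacks. A constant scope maps to zeros, never NaN. Labels use
0 = unannotated with classes from 1, matching label-layer conventions in
interactive viewers. Models retrain from scratch on every call — correctness
over incremental speed.

## 4. The scribble generator

Human-like scribbles are synthesized from a ground-truth mask per class,
with the class budget proportional to class area (this makes the global
annotated fraction the single density parameter). Three stroke sources:

1. **ridge** — random walks along the primary (medial-axis, Zhang–Suen
   thinning) skeleton;
2. **boundary-parallel** — walks along the secondary skeleton, i.e. the
   skeleton of the mask after subtracting the primary skeleton dilated by
   the stroke width (the dilation prevents the two line types overlapping);
3. **boundary-perpendicular** — steepest-descent paths from a skeleton pixel
   down the 4-connected distance-to-background transform to the boundary.
   4-connectivity is chosen so a path from the centre of a disk of radius
   $r$ has length $\approx r$ (8-connected distances undercount diagonals
   by $\sqrt 2$).

Strokes are cut to a length drawn from `length_range`, dilated to `width`,
intersected with the class mask (purity by construction: an annotated pixel
always carries the ground-truth label), and accumulated until the budget is
met; the last stroke is trimmed, which is why achieved density tracks the
request to well within the ±10% contract. When a source is exhausted the
generator falls back to other types and, after 200 consecutive stalls,
stops with a warning reporting the achieved density. Everything is driven by
one seeded RNG; identical config ⇒ identical mask.

Presets reflect the benchmark's dataset-specific styles: `cell` (many short
1-px strokes), `natural` (fewer long 2-px strokes), `histology`
(medium 2-px strokes, also the default width/length). Benchmark densities
default to 0.25%, 1.0% and 2.5% of image pixels.

Dataset preparation implements the reference filtering rules
(`require_class0`, `multi_class_only`, `min_class_area(0.01)`) with reason
codes, and `window_image()` reads "largest value ≥ 1400 px that evenly
divides the dimension" as the largest *proper* divisor — taking the
dimension itself would mean no windowing at all — falling back to the full
dimension when no proper divisor qualifies (e.g. prime dimensions). The
class-0 rule's direction is ambiguous in its source and is implemented
verbatim (drop masks with no class-0 pixels) as a configurable rule.

mIoU averages $|P_c \cap G_c| / |P_c \cup G_c|$ over all classes (> 0)
present in either mask; scribbled pixels are *included* by default, with an
`exclude` argument for the stricter protocol (whether the original study
excluded them is unstated).

## 5. Synthetic fixtures: what a green test establishes

Each `make_fixture()` kind states a world solvable by a specific extractor
class: `intensity_separable` (class means ≥ 4 noise SD apart on a Voronoi
partition), `texture_separable` (equal means ± < 0.05, autocorrelation
lengths differing ≥ 3×; generated at ratio 8 because near the 3× floor the
per-pixel filter responses of the two textures overlap too much for *any*
pixel classifier to stay reliably above 0.9 mIoU), `semantic_context`
(below), `instances` (disks for instance→semantic conversion), `volume3d`
(ellipsoids in noise), and `multichannel` (XOR-coupled channels whose
marginals are class-identical). They are textured, seeded and generated in
memory — they do **not** emulate optics, shading, or annotation noise of
real microscopy; a green end-to-end test establishes that the pipeline
recovers a planted signal at stated SNR, not performance on any external
dataset.

## 6. The local-vs-context dichotomy at desk scale

`semantic_context` plants two 64×64 squares with *identical* interiors, one
in a bright and one in a dark half of a 256×320 image: class identity of a
deep interior pixel is determined solely by the enclosing environment.
Local features cannot exceed ≈ 0.5–0.7 mIoU here; concatenating large-window
context statistics lifts a random forest above 0.85 (both measured in the
acceptance suite, three seeds).

We initially tried to use the randomly initialized CNN pyramid as the
context arm and document why it was rejected: the channels of a
random-weight network at large receptive field are smooth spatial ramps, so
a tree ensemble trained on skeleton-sampled scribbles carves value intervals
that contain *no background training pixels* and misroutes entire unseen
regions; with dense random annotations the same features classify almost
perfectly (mIoU ≈ 0.98), so the failure is an interaction between feature
geometry and scribble placement, not information content. Pretrained
backbones avoid this because their features are semantically quantized;
shipping or downloading weights is out of scope. The window-statistics
extractor provides the same "environment identity" signal in a form that is
monotone in the environment, which is what sparse-scribble tree training
needs; the CNN pyramid remains fully implemented and contract-tested. The
context arm uses the `cell` scribble preset: at 1% density the default long
strokes amount to only a handful of background strokes on this fixture, and
whole regions can go uncovered — a sampling artifact that would measure
stroke granularity, not feature quality.

## 7. Numerical choices and degenerate inputs

* Percentile = sort-based type-7 interpolation; constant scopes → zeros.
* Filters on images smaller than 2 px per side are refused.
* Argmax ties → lowest class id; majority-filter ties → centre label.
* Class probabilities are normalized per pixel (sum to 1 within 1e-6).
* The `.pseg` archive stores a JSON manifest (format_version, extractor
  spec, normalization, classes, seed) plus an R-serialized classifier blob;
  loading checks the version and names missing sections. The blob is not
  portable across languages (a documented non-goal).
* PNG label I/O is 8-bit (class ids ≤ 255; use PGM beyond); the environment
  has no TIFF/zarr reader, so stacks use a plain-text `.sst` format and
  larger-than-memory prediction uses the plane-source callback.

## 8. Known limitations

* No pretrained backbones, hence no claims about semantic segmentation of
  natural images; the toy backbones validate machinery, not representation
  quality.
* The scribble generator's strokes follow skeleton geometry; real human
  scribbles are sloppier and may cross boundaries, which the generator never
  does.
* Tiling of whole-image-context extractors is approximate by construction
  and therefore off by default.
* Multi-projection extraction assumes isotropic-enough voxels.
* Runtime columns in benchmark tables are wall-clock measurements and vary
  between runs; all other outputs are deterministic given seeds.
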