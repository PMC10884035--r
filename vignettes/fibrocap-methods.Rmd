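---
title: "Fibrous-cap segmentation and morphometrics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibrous-cap segmentation and morphometrics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Thin-cap fibroatheroma (TCFA) — a lipid-rich coronary lesion whose fibrous
cap (FC) is thinner than 65 µm at its thinnest point — is a major rupture-risk
phenotype. Intravascular optical coherence tomography (IVOCT) resolves the
cap at ~5 µm radial pixel pitch, but manual delineation of caps over
hundreds of frames per pullback is impractical. `fibrocap` implements a
fully automated pipeline in the native polar (r, θ) acquisition domain:

1. **Preprocessing** — guidewire-shadow detection, lumen segmentation,
   per-A-line pixel-shifting so the lumen surface sits at radial index zero,
   cropping to the first 200 radial pixels (~1 mm of penetration), and a
   7×7, σ = 1 Gaussian filter.
2. **Augmentation** — loss-free spiral rotation offsets of the raw helical
   A-line stream (default six offsets of 80 A-lines), and stochastic
   flip/intensity jitter on preprocessed images.
3. **Segmentation** — an encoder–decoder residual network with group
   normalization trained with the soft Dice loss and AdamW, optionally
   initialized from a network pretrained on a calcification source task
   (transfer learning).
4. **Postprocessing** — morphological opening with a radius-3 disk followed
   by hole filling under 4-connectivity, with θ treated circularly.
5. **Morphometrics** — per-A-line cap thickness, arc angle, cross-sectional
   and luminal surface area, TCFA classification, thickness heatmaps, and
   agreement statistics (Bland–Altman, coefficient of variation).

Because the clinical registries behind the original method are not public,
the package ships a first-class synthetic phantom generator that emulates
their geometry and serves as the test bed for every stage.

## The phantom generator

`generate_pullback()` renders polar pullbacks with a piecewise-constant
tissue model: per-class mean reflectance (lumen background 0.02, vessel
wall 0.45, cap 0.70, lipid 0.12), exponential depth attenuation
(1.5 mm⁻¹), and multiplicative gamma speckle with configurable contrast
(default 0.25). The lumen radius varies smoothly in θ and along the
pullback; a guidewire shadow band (near-zero intensity) drifts slowly
across frames; the cap is a signal-rich layer at the lumen surface over a
signal-poor lipid pool, with a smooth thickness field drawn from the
configured range and rounded to whole pixels so that *mask column count ×
pixel size equals the recorded truth thickness exactly*. Lesions may
straddle the θ = 0 seam to exercise wraparound handling.
`generate_calcific_pullback()` renders the transfer-learning source task:
a sharply delineated low-backscatter body with a bright border.

What the phantom does **not** model: catheter optics, realistic OCT point
spread, thrombus, side branches, eccentric catheter position, or
calibrated FC/lipid contrast (the literature gives only qualitative
appearance descriptions, so contrast levels are free parameters). Passing
tests on phantoms therefore demonstrates the correctness of the pipeline's
mechanics and its behaviour under controlled geometry — not clinical-grade
segmentation accuracy on patient data.

Seeding: one master seed drives pullback-level draws; each frame uses an
arithmetically derived substream, so any frame is bit-reproducible
independently of how many frames are requested.

## Preprocessing choices

* **Guidewire detection**: A-lines whose depth-averaged intensity falls
  below 50 % of the frame median are grouped into wrapped runs; the darkest
  run with width 10–60 A-lines is returned. The upstream algorithm this
  step replaces is described only by citation in the source method, so the
  band-width and deficit defaults are package choices.
* **Lumen segmentation**: the original method delegates to a previously
  trained deep network that is not available. The default backend scores a
  step-edge filter (mean intensity just abluminal minus just luminal,
  half-window 5 px) and regularizes by dynamic programming with an L1
  penalty (λ = 0.05 intensity units per pixel of radial jump). Messages are
  passed around the circle twice so the result is stationary and
  rotation-equivariant. The backend is pluggable (`lumen_backend`
  argument), so a learned model can be substituted. On phantoms the DP
  detector stays within 2 px of truth.
* **Pixel-shifting** stores the boundary as the per-A-line shift record;
  the map is invertible on retained pixels, and the same record transforms
  label masks (image/label synchrony).
* **Gaussian filter**: θ is circular in acquisition geometry, so the filter
  wraps in θ and mirrors in r; a kernel truncated at 7×7 and normalized to
  unit sum keeps constants invariant.
* **Normalization**: per-pullback min–max to [0, 1], preserving inter-frame
  contrast (the scope of normalization is unstated upstream; per-image
  scaling would erase frame-to-frame brightness differences).
* Guidewire A-lines are zero-filled rather than removed (the "black strip"
  convention), and excluded from evaluation counts because they carry no
  tissue truth.

## The network

A SegResNet-style fully convolutional encoder–decoder: initial 3×3
convolution (16 filters by default) with channel-wise spatial dropout
(0.2); per level, pre-activation residual blocks (GroupNorm → ReLU → 3×3
conv, twice, plus identity); strided 3×3 convolutions halve resolution and
double features between the 4 levels (1, 2, 2, 4 encoder blocks); the
decoder has one block per level, reached by a 1×1 convolution that halves
features, bilinear ×2 upsampling, and an additive encoder skip; a 1×1
convolution and sigmoid end the network. There is no variational
auto-encoder branch. The group count (8), level count and block counts are
the conventional values for this architecture family. Input sizes not
divisible by 2^(levels−1) are padded symmetrically and cropped after the
head; 200 × 448 divides cleanly.

The upstream description mentions softmax outputs but a sigmoid head for
what is a binary task; the sigmoid + binary soft Dice combination is
adopted, matching the architecture diagram. The Dice smoothing constant is
1e-6. The prediction threshold (0.5) is a package default. Plurality
voting resolves ties to negative — conservative against false positives,
consistent with the postprocessing intent.

No deep-learning framework is available to R in this environment, so the
package carries its own compact CNN engine: im2col + BLAS convolutions in
C++ (Rcpp/RcppArmadillo) and hand-derived backward passes for every layer
(group norm, ReLU, bilinear upsampling, dropout, sigmoid + Dice). The
gradients are verified against central finite differences in the test
suite (worst relative error ~1e-7 on a small configuration). AdamW uses
the reference hyperparameters by default (lr 1e-5, ε 1e-9, decoupled
weight decay 1e-6, L2 of 1e-6 on convolution kernels, batch 64, up to 600
epochs), with early stopping after 10 consecutive validation epochs
without strict improvement and restoration of the best-validation weights.
Transfer learning copies all weights from an architecturally identical
pretrained model by default (`include_decoder = FALSE` gives the
encoder-only mode), and per-layer learning-rate multipliers implement
layer-wise fine-tuning; uniform fine-tuning is the documented default.

## Morphometrics

Thickness is measured radially along each A-line in the shifted frame as
the inclusive span of the cap column times the radial pixel size. The
upstream wording ("along the abluminal boundary from the luminal boundary
at each A-line") is ambiguous between radial and surface-normal distance;
radial is chosen as it matches the A-line phrasing and the polar
measurement domain. Cross-sectional area uses the polar area element
r·Δr·Δθ at the *true* radius restored through the shift record — naive
pixel counting would bias areas because polar pixel area grows with r.
Surface area is the luminal arc length of the cap times the frame pitch,
summed over frames. Arc angle is the A-line count × 360/448 ≈ 0.8036°.
Cap regions are θ-wrapping connected components per frame, linked across
consecutive frames when their angular extents overlap; lesion length is
the linked frame span times the frame pitch. TCFA uses the strict
`min thickness < 65 µm` rule, evaluated per lesion (per-pullback averaging
is also available since the upstream reproducibility analysis does not
specify the averaging unit). The coefficient of variation uses the
population standard deviation, so repeats {90, 110} give exactly 0.1.

## Evaluation

Pixel-wise PPV, NPV, sensitivity, specificity, accuracy and Dice are exact
ratio evaluations with zero-denominator cases flagged `NA` rather than
reported as 0 (silently zeroing them would bias fold means). Fold metrics
pool pixels within a fold by default; per-frame macro-averaging is
available. Cross-validation splits are made at the pullback level into
train/validation/test rotations (60/20/20 with 5 folds), with test groups
pairwise disjoint and covering.

## Problem sizes used by the tests and the acceptance script

Training-dependent checks run on reduced phantom geometry chosen so the
full suite completes in minutes on a single CPU; these sizes are the
package's benchmark definitions:

* **Thickness recovery**: 50 held-out pullbacks of 3 frames, 300 × 64 raw
  → 48 × 64 preprocessed at the standard 5 µm/0.2 mm pitch; the model is
  8-filter, 3-level, trained 10 epochs (Adam-scale learning rate 1e-3,
  appropriate to a small network trained minutes on CPU; the 1e-5/600-epoch
  reference schedule remains the package default for full-scale training)
  on 300 frames from 30 disjoint pullbacks. The model-based thickness error
  counts missed and spurious A-lines at full weight (missing side treated
  as 0 µm), so it is a conservative figure.
* **Transfer benchmark**: 32 × 48 frames, 4-filter model; the source model
  is pretrained on 48 calcification frames; both arms fine-tune/train on 16
  frames with 16 validation frames, patience 3, cap 12 epochs, 10 paired
  seeds. The scarce-label regime is where transfer learning demonstrably
  helps at this scale (mirroring the sample-efficiency behaviour of the
  full-scale method); with abundant phantom labels a scratch model of this
  size converges so quickly that there is nothing left for transfer to
  speed up. Encoder-only initialization is used in the benchmark: the
  calcification source task has inverted lesion contrast (dark body, bright
  rim) relative to the bright cap, and copying its decoder/head measurably
  biases early fine-tuning on phantoms, whereas the encoder's generic
  edge/texture features transfer cleanly.

## Numerical and degenerate-input policies

* Uniform frames yield an empty guidewire set; all-dark frames raise a
  "no detectable lumen" error rather than returning garbage.
* `crop_depth` refuses frames shallower than the crop; `pixel_shift`
  refuses out-of-range boundaries; already-preprocessed pullbacks cannot
  be preprocessed again.
* Opening pads by twice the disk radius (background beyond the r borders,
  circular wrap in θ) so the cropped result equals morphology on the
  unbounded circular domain; hole filling defines "border" on the r axis
  only. The full operation is idempotent.
* Empty masks quantify to zero area, an empty lesion table, and all-`NA`
  thickness; zero-mean inputs make the coefficient of variation `NA`.
* Ties in plurality voting go to negative; ties in guidewire band search
  go to the darkest, then first, band.

## Known limitations

* Phantom appearance is not calibrated to clinical data; absolute Dice on
  phantoms (≈0.95–0.98 for the small benchmark models) says nothing about
  the clinical Dice of a full-scale model.
* The DP lumen detector assumes a single dominant step edge per A-line; it
  has no notion of blood artifacts or stent struts.
* The CNN engine is CPU-only and single-threaded beyond BLAS; it is sized
  for desk-scale experiments, not 600-epoch clinical training runs.
* Longitudinal lesion linking uses angular overlap of consecutive frames
  only; a lesion vanishing for one frame splits in two.
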