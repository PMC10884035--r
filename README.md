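# fibrocap

Fully automated fibrous-cap (FC) segmentation and morphometrics for
polar-domain intravascular optical coherence tomography (IVOCT).

Thin-cap fibroatheroma — a lipid-rich coronary lesion whose fibrous cap is
thinner than 65 µm at its thinnest point — is a key rupture-risk phenotype.
IVOCT resolves the cap at ~5 µm radial pitch, but manual delineation across
hundreds of frames per pullback is impractical. `fibrocap` implements the
full analysis chain in the native polar (r, θ) domain, for image-analysis
researchers working on coronary plaque quantification:

* **Preprocessing**: guidewire-shadow detection, dynamic-programming lumen
  segmentation, per-A-line pixel-shifting so the lumen surface sits at
  radial index 0, cropping to the first 200 radial pixels (~1 mm), and a
  7×7, σ = 1 Gaussian filter — a raw 968 × 448 frame becomes 200 × 448.
* **Augmentation**: loss-free spiral rotation offsets of the raw helical
  A-line stream (six offsets of 80 A-lines by default) and stochastic
  flip/intensity jitter.
* **Segmentation**: an encoder–decoder residual network with group
  normalization (initial 3×3 convolution with 16 filters and dropout 0.2;
  strided-convolution downsampling; bilinear-upsampling decoder with
  additive skips; sigmoid head), trained with the soft Dice loss
  `1 − (2Σpy + ε)/(Σp + Σy + ε)` and AdamW (lr 1e-5, ε 1e-9, weight decay
  1e-6, batch 64, ≤600 epochs, early stopping after 10 non-improving
  validation epochs), with optional transfer learning from a calcification
  source task. The CNN engine (im2col/BLAS convolutions in C++, hand-derived
  backward passes) is part of the package.
* **Postprocessing**: morphological opening with a radius-3 disk and hole
  filling under 4-connectivity, with θ treated circularly.
* **Quantification**: per-A-line thickness (column span × pixel size), arc
  angle (A-lines × 360/448°), polar-exact cross-sectional area (Σ r·Δr·Δθ),
  luminal surface area (arc length × frame pitch), TCFA classification
  (min thickness < 65 µm), thickness heatmaps with PLY mesh export, and
  agreement statistics: pixel-wise PPV/NPV/sensitivity/specificity/accuracy/
  Dice (= 2TP/(2TP+FP+FN)), pullback-level five-fold cross-validation
  splits, plurality-vote ensembling, Bland–Altman bias ± 1.96 SD, and
  coefficients of variation.

The clinical registries behind the original method are private, so the
package ships a first-class synthetic phantom generator (lumen, guidewire
shadow, signal-rich cap over signal-poor lipid pool, gamma speckle, exact
ground-truth thickness fields) that drives all tests and examples. See the
methods vignette (`vignettes/fibrocap-methods.Rmd`) for the model details
and design decisions.

## Worked example

```r
library(fibrocap)

# simulate a 10-frame pullback with a lipid lesion and ground truth
sim <- generate_pullback(phantom_config(n_frames = 10, seed = 42))
sim$pullback
#> polar_pullback: 10 frame(s) of 968 x 448 (r x theta), raw
#>   pixel_size_r = 5 um, frame_pitch = 0.2 mm

# five-step preprocessing
pp <- preprocess_pullback(sim$pullback)
dim(pp$pullback$frames)
#> [1] 200 448  10

# measure cap thickness from the truth masks carried into shifted space
masks <- preprocess_mask(sim$truth$fc_mask_raw, pp$shifts)
th <- aline_thickness(masks, pixel_size_r = 5)
geom <- list(pixel_size_r = 5, frame_pitch = 0.2,
             lumen_boundary = pp$boundaries, shifts = pp$shifts)
region_summary(masks, th, geom)$lesions[, c("length_mm",
  "mean_thickness_um", "min_thickness_um", "max_arc_deg", "tcfa")]
#>   length_mm mean_thickness_um min_thickness_um max_arc_deg  tcfa
#> 1         2          113.5723               75    139.0179 FALSE
```

The lesion spans all 10 frames (2 mm at 0.2 mm pitch), has a ~114 µm mean
and 75 µm minimum cap thickness with a 139° maximum arc, and is not a TCFA
under the strict `< 65 µm` rule. Training, prediction, postprocessing and
evaluation are orchestrated end-to-end by `run_pipeline()`
(`default_run_config()` carries the reference parameters), or from a shell
via the thin CLI at `inst/cli/fibrocap`.

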