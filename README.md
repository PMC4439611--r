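# boneseg

Automatic segmentation of the **humeral head** in 2D axial
proton-density (PD) weighted shoulder MR slices.

PD-weighted shoulder MRI shows bone and soft tissue — including
post-traumatic bone edema — in a single sequence, but it has low SNR, a
scanner bias field, and a smooth transition zone between bone and soft
tissue instead of crisp edges. `boneseg` implements a full pipeline for
delineating the humeral head under these conditions:

* **SRAD denoising** — speckle-reducing anisotropic diffusion
  `∂I/∂t = div(c(q)∇I)`, with the diffusion gated by the instantaneous
  coefficient of variation `q` and a noise scale `q₀ = sd(z)/z̄`
  estimated on the tissue *foreground* (appropriate for Rician MR noise
  over an air background);
* **homomorphic bias correction** — log-domain Gaussian high-emphasis
  filtering of the multiplicative illumination model `f = i·r`;
* **circular Hough transform** — automatic detection of the
  quasi-circular head, an enlarged circular ROI, and the initial contour
  (removing the initialization sensitivity of region-based models);
* **two level-set engines** — ACWE (Chan–Vese,
  `∂φ/∂t = δ_ε(φ)[μκ − ν − λ₁(u₀−c₁)² + λ₂(u₀−c₂)²]`, parameters
  μ = 0.2, ν = 1, λ₁ = 0.7, λ₂ = 1, ε = 1.5, 650 iterations) and a
  signed-pressure-force model
  (`spf = (I − (c₁+c₂)/2)/max|I − (c₁+c₂)/2|`, balloon force α, 5×5
  Gaussian regularization with σ = 2, 120 iterations);
* **clustering baselines** — 2-class Gaussian-mixture (EM, K-means
  initialized) and fuzzy C-means (m = 2) on the ROI intensities;
* **anatomical postprocessing** — shoulder-side detection, sector-wise
  morphological opening that removes scapula/tendon attachments,
  edema-hole filling, red boundary overlay;
* **evaluation** — Sørensen–Dice `2|A∩B|/(|A|+|B|)` against reference
  masks, before and after postprocessing.

Since no public PD shoulder dataset exists, the package includes a
seeded **shoulder phantom generator** (`phantom_spec()`, `make_phantom()`,
`make_cohort()`) that emulates normal, edematous, and Hill-Sachs humeral
heads with a glenoid arc, a tendon band, a smooth multiplicative bias
field, the PD transition zone, and Rician noise. The entire test suite
runs on these phantoms.

## Worked example

```r
library(boneseg)

# a standard corrupted phantom: Rician noise at 10% of head intensity,
# bias-field amplitude 0.3
ph <- make_phantom(phantom_spec(noise_sigma = 20, bias_amplitude = 0.3,
                                seed = 11))

out <- run_pipeline(ph$image, pipeline_config(method = "acwe"),
                    truth = ph$truth)
out$roi
#> circle_roi: center (128.0, 110.0), radius 40.0 px, ROI radius 48.0 px
out$record
#>   method  dice_pre dice_post iterations
#> 1   acwe 0.9680508 0.9864596        168
```

The detected circle matches the phantom's true head (center (128, 110),
radius 40) exactly; ACWE inside the enlarged ROI overlaps the true head
mask with Dice 0.968, rising to 0.986 after the scapula/tendon
suppression and hole filling. `out$result$boundary` holds the final
closed boundary polygon; `save_overlay()` renders it in red over the
slice, and `save_mask()` / `write_result_json()` export the mask and a
machine-readable record.

Real slices enter the same way: `load_image("slice.dcm")` reads
single-frame grayscale DICOM (rescale slope/intercept applied, negatives
clamped), 8/16-bit PNG, or TIFF.

### Command line

```sh
Rscript inst/cli/boneseg.R make-phantom --group edema --seed 7 \
    --image-out slice.tif --truth-out truth.png
Rscript inst/cli/boneseg.R run --image slice.tif --truth truth.png \
    --method acwe --out results/
Rscript inst/cli/boneseg.R detect-roi --image slice.tif
```

`run` writes `mask.png`, `overlay.png`, and `result.json`; a YAML file
passed via `--config` mirrors the `pipeline_config()` blocks.

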