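---
title: "Morphology-guided MSI annotation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-guided MSI annotation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the model implemented by `morphomsi`, every
parameter with its unit, default and rationale, the design of the synthetic
fixture, the numerical conventions, and the known limitations. The code
chunks are not evaluated at build time; all of them run as written (the
full pipeline takes about 90 s on one CPU).

## 1. The pipeline

MALDI mass spectrometry imaging (MSI) of a thyroid tissue microarray (TMA)
yields one spectrum per 20 µm raster spot. Diagnostic peptide signal comes
from the cell-rich (epithelial) tissue; colloid, stroma and background
contribute matrix-adduct and trypsin-autolysis interferents and dilute the
signal. The pipeline replaces coarse, manually drawn regions of interest
(ROIs) with ROIs derived from the co-registered H&E image:

1. **Features.** Colour deconvolution of the H&E into a hematoxylin channel
   plus the raw R, G, B channels; for each channel a Gaussian smoothing and
   a Gaussian-weighted local standard deviation ("weighted deviation") at
   two scales. 4 channels × 2 kinds × 2 scales = 16 features per pixel.
2. **Pixel classifier.** A linear softmax on the standardized features,
   16 × 2 = 32 parameters without bias, trained by full-batch gradient
   descent on small annotated squares (classes `cell_rich`,
   `non_cell_rich`). Probabilities are thresholded at 0.5; objects and
   holes under 7 µm² are removed/filled; surviving 8-connected components
   are vectorised into polygons with holes.
3. **Label transfer.** The per-core diagnosis polygons drawn by the
   pathologist are rasterized over the detections; each detection fragment
   inherits the diagnosis that covers it, and detections with no overlap
   are dropped.
4. **Coregistration.** An affine transform image px → MSI µm is fitted to
   control points by least squares, then refined by exhaustive translation
   search (step 5 µm) maximising the Pearson correlation between the H&E
   tissue mask sampled at the spot centres and the ion image of the
   collagen-derived reference peak at m/z 1459.688.
5. **Tiling.** Labelled detections are buffered outward by 4 µm (raster
   dilation), mapped to the MSI frame, and every measured spot whose centre
   falls inside the geometry joins the "PC" ROI. "FC" (full core, from
   automatic dearraying) and "PAT" (pathologist polygons) ROIs are built
   the same way for comparison; PC is restricted to FC so the three types
   are nested where the science expects them to be.
6. **Spectral comparison.** All spectra are RMS-normalized once. Per ROI
   type: pooled mean spectrum → peak picking; interferent-panel scoring;
   PCA on extracted peak intensities; per-feature Mann–Whitney ROC between
   every diagnosis pair.

```{r}
library(morphomsi)
res <- run_pipeline(run_config(seed = 1), "run1")
res$summary$discriminatory_counts
```

## 2. Parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `image_px_size` | 0.44 | µm/px | typical 20× whole-slide scan resolution |
| `msi_pitch` | 20 | µm | MSI raster step; one spectrum per 20 × 20 µm spot |
| `sigmas` | 2, 4 | px | smoothing/texture scales ≈ 0.9 and 1.8 µm, matching nuclear texture at 0.44 µm/px |
| `min_object_um2`, `min_hole_um2` | 7 | µm² | sub-nuclear debris filter for detections |
| `threshold` | 0.5 | – | argmax for a two-class softmax |
| `buffer_um` | 4 | µm | compensates classifier edge erosion before tiling to the 45× coarser grid |
| `snr_min` | 6 | – | peak-picking signal-to-noise threshold |
| `rel_int_min` | 0.003 | fraction | 0.3 % of base peak, relative-intensity gate |
| `baseline_window` | 50 | Da | windows for the percentile baseline and MAD noise |
| `min_sep_da` | 0.25 | Da | minimum apex separation (isotope-width scale) |
| `tol_ppm` | 20 | ppm | peak matching / extraction half-window |
| `auc_hi`, `auc_lo` | 0.7, 0.3 | – | discriminatory AUC bounds (either direction) |
| `pca_components` | 5 | – | components retained after unit-variance scaling |
| `ref_mz` | 1459.688 | Da | collagen-derived reference ion for registration |
| `search_radius_um`, `refine_step_um` | 30, 5 | µm | refinement search range and step (¼ pitch) |
| `epochs`, `learning_rate` | 500, 1 | – | full-batch gradient descent; deterministic, converges well past separability on standardized features |

The interferent panel contains ten HCCA matrix-adduct m/z values (839.08,
845.09, 855.05, 861.06, 867.08, 1036.13, 1044.09, 1054.08, 1060.06,
1066.08) and three trypsin-autolysis peptides (842.51, 1045.56, 1220.64).

## 3. Peak picking: the S/N definition

`pick_peaks()` deliberately separates the *signal* and *noise* estimators:

- **Baseline**: 10th percentile per 50 Da window, linearly interpolated,
  then **debiased** by adding `-qnorm(0.1) × noise`. The q-quantile of pure
  noise sits `qnorm(q)·σ` below the true baseline, so the raw percentile
  systematically underestimates it; without the correction every
  baseline-subtracted apex is inflated by ≈ 1.28 noise units, enough to
  push a small fraction of 3σ fluctuations past the S/N 6 gate. The MAD
  noise estimate is shift-invariant, so the correction does not feed back
  into itself.
- **Apex height**: measured on a lightly Savitzky–Golay-smoothed signal
  (quadratic, 5-point window), which suppresses single-sample noise spikes.
- **Noise**: 1.4826 × MAD of the *raw* baseline-subtracted residuals per
  window. Using raw (not smoothed) residuals keeps the denominator an
  honest estimate of per-point noise.

The combination is conservative by construction: a peak planted at
amplitude 3σ measures S/N ≈ 2.3 ± 0.7 and essentially never crosses the
threshold of 6, which the acceptance suite verifies on 200 synthetic
spectra. Apex m/z is refined by a three-point parabola on the smoothed
signal. The last baseline window absorbs any remainder of the m/z range so
no window is degenerately narrow (a one-bin window has MAD 0 and would
fabricate infinite S/N).

`extract_intensity_matrix()` uses the same baseline and falls back to the
nearest m/z bin when the ppm window contains no grid point — at 20 ppm,
windows below m/z ≈ 1250 are narrower than the 0.05 Da axis step, and
without the fallback a feature could silently read as zero.

## 4. The synthetic fixture

The generator (`fixture_phantom()`, `spectrum_model()`,
`simulate_fixture()`) produces paired data with known ground truth.

**Geometry.** A 2 × 2 grid of circular cores (radius 100 µm, spacing
250 µm) at 0.44 µm/px → a 1136 × 1136 px H&E image. Each core carries one
diagnosis (PTC, FVPTC, NIFTP, FA) and a centred hexagonal packing of
follicles: an 18 µm colloid lumen inside a 12 µm cell-rich epithelial rim,
jittered by ±2 µm. The H&E rendering colours background, stroma, colloid
and rim distinctly and adds strong high-frequency noise only inside the
rims — so the weighted-deviation features, not just colour, carry class
information.

**Annotations.** Training squares (≈ 3 µm half-width) are sampled from the
cell-rich mask and, for the negative class, in equal parts from colloid,
stroma, background *and the perifollicular band* just outside the rims.
The band stratum mirrors how an annotator marks confusable boundary tissue;
without it the texture features bleed past the rim edge and the classifier
over-segments outward. The pathologist polygons are a morphological closing
(r = 15 µm) of each core's follicular region — deliberately generous, the
way a human outlines "the lesion", including colloid.

**Spectra.** Each measured spot gets
`baseline + Σ Gaussian peaks (σ = 0.06 Da) + N(0, 0.2)` on an m/z axis
700–3000 at 0.05 Da steps. Peptide amplitudes scale with the spot's
cell-rich area fraction (estimated on a 7 × 7 sub-grid through the inverse
of the planted affine transform); HCCA interferents scale with
`1 + 3 × colloid fraction`; trypsin peaks are uniform; the m/z 1459.688
structural peak scales with total tissue fraction. Per diagnosis there are
two shared peptides (944.53, 1325.75), a strong unique peptide (amplitude
60), a mid unique peptide (25), and a **trace** unique peptide (0.85).

The trace amplitude was derived analytically so that, in the pooled
ROI-type mean spectrum (four diagnoses pooled, so each trace is diluted
4-fold), the trace peaks sit *near* the 0.3 % relative-intensity and S/N 6
gates: ROIs with a higher cell-rich fraction (PC) lift them over the
thresholds, coarser ROIs (FC) leave most of them below. On the default
fixture the FC list contains 25 peaks (1 trace), PAT 27 (3 traces), PC 28
(all 4) — the "PC gains peaks and unique m/z" behaviour, emerging from
composition rather than from hard-coding.

**Planted transform.** The image-to-MSI transform is
`A = 0.44·R(0°), b = (24, 12) µm`, recovered during the run from corner
control points and the reference-ion refinement.

## 5. Numerical conventions

- Pixels are 0-based with pixel-centre sampling; row index is y (down),
  column is x. MSI spot (i, j) has its centre at `(i + 0.5, j + 0.5) ×
  pitch` µm; imzML stores 1-based coordinates.
- Polygon geometry is exact pixel-edge tracing (interior on the left,
  outer rings positive area) and scanline even-odd rasterization under the
  pixel-centre rule, so `mask → polygons → mask` round-trips identically;
  connected components use 8-connectivity for objects and 4-connectivity
  for holes.
- imzML I/O is hand-rolled (continuous and processed mode, 32/64-bit,
  UUID + MD5 verification) because no suitable R reader is available in
  the dependency set; it is cross-checked against the Python `pyimzml`
  parser in the test suite. Continuous-mode round trips are bit-exact.
- The rank-sum AUC uses the Mann–Whitney midrank formulation
  `(R_pos − n₁(n₁+1)/2)/(n₁n₂)`, ties counted one half, verified against
  brute-force pair counting to 1 × 10⁻¹².

## 6. Problem sizes and runtime

On the default fixture (one CPU): feature stack ≈ 13 s (1136² px × 16
features), classifier training ≈ 3 s (1 470 training pixels, 500 epochs),
prediction + post-processing ≈ 11 s, MSI rendering ≈ 8 s (385 spectra ×
46 001 bins), whole pipeline ≈ 90 s. The test suite runs in ≈ 3 min.

## 7. Limitations

- The classifier is linear; it recovers the fixture's cell-rich mask with
  IoU ≈ 0.96 but real H&E would likely need non-linear features or more
  scales. The architecture (and its 32-parameter budget) is a deliberate
  floor, not a recommendation.
- Registration refinement searches translations (optionally a few fixed
  rotations); shear or local distortion is out of scope.
- The fixture's spectral model is additive Gaussian peaks with white
  noise; it does not simulate detector saturation, isotope envelopes,
  mass-dependent resolution, or chemical background drift. Directional
  claims verified on it are necessary, not sufficient, evidence for real
  data.
- ROC analysis applies no multiple-testing correction, matching the
  screening (not confirmatory) use of the AUC bounds.
- Processed-mode imzML is resampled onto the union m/z grid by linear
  interpolation on read; bit-exactness is guaranteed only for
  continuous mode.
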