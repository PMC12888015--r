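# morphomsi

Morphology-guided annotation of MALDI mass spectrometry imaging (MSI) data
from thyroid tissue microarrays (TMAs), as an open, fully scripted R
pipeline.

## The problem

MALDI-MSI acquires a mass spectrum at every spot of a 20 µm raster over a
tissue section. The standard way to define regions of interest (ROIs) on a
TMA is coarse: either the whole circular core ("full core", FC) or a
polygon drawn free-hand by a pathologist ("PAT"). Both include material
that carries no diagnostic proteomic signal — colloid, stroma, background —
and that material contributes matrix-adduct (HCCA) and trypsin-autolysis
interferent peaks while diluting the tryptic peptide signal of the
epithelium.

`morphomsi` implements the alternative: use the co-registered H&E image to
find the cell-rich (epithelial) tissue at sub-micrometre resolution with a
small supervised pixel classifier, transfer the pathologist's per-core
diagnosis onto those detections, and tile the result down to the MSI grid
("PC" ROIs, for pixel classifier). The three ROI types are then compared
spectrally: RMS normalisation, peak picking at S/N ≥ 6 and ≥ 0.3 % relative
intensity, an interferent panel, per-ROI PCA, and per-feature rank-sum
(Mann–Whitney) ROC analysis with AUC > 0.7 or < 0.3 as the discriminatory
criterion.

The expected, directional result — reproduced end-to-end on the package's
synthetic fixture — is that PC ROIs contain fewer spots than PAT and FC,
show lower interferent intensity, higher peptide signal-to-noise, more
peaks passing the picking thresholds, and more discriminatory m/z features
between diagnoses.

## What is in the package

| Module | Exported entry points |
|---|---|
| Synthetic fixture | `fixture_phantom()`, `spectrum_model()`, `render_he_image()`, `render_msi_cube()`, `simulate_fixture()` |
| H&E features | `deconvolve_stains()`, `gaussian_filter()`, `weighted_deviation_filter()`, `compute_features()` |
| Pixel classifier | `pixel_classifier()` (+ `print`/`summary`/`coef`/`predict` methods), `postprocess_detections()`, JSON I/O |
| TMA / ROIs | `dearray()`, `transfer_labels()`, `tile_to_msi()`, `build_roi_types()`, `roi_set()` |
| Registration | `fit_affine()`, `refine_by_ion_image()`, `ion_image()`, `affine2d()` |
| Spectra | `read_imzml()`, `write_imzml()`, `rms_normalize()`, `pick_peaks()`, `match_peaks()`, `extract_intensity_matrix()` |
| Comparison | `interferent_panel()`, `score_interferents()`, `roi_pca()`, `rank_auc()`, `roc_analysis()`, `count_discriminatory()` |
| Orchestration | `run_config()`, `run_pipeline()`, `inst/cli/morphomsi.R` |

Everything runs on a synthetic but physically structured fixture: a 2×2 TMA
of 200 µm cores with hexagonally packed follicles (colloid lumen + cell-rich
epithelial rim), one diagnosis per core (PTC, FVPTC, NIFTP, FA), an H&E
rendering with per-stratum colour and texture, and an imzML cube whose
spectra mix diagnosis-specific tryptic peptides (scaling with the cell-rich
fraction of each spot), colloid-enriched HCCA interferents, uniform trypsin
autolysis peaks, and a collagen-derived structural peak at m/z 1459.688
used as the registration reference ion.

## Worked example

```r
library(morphomsi)

cfg <- run_config(seed = 1)        # all documented defaults
res <- run_pipeline(cfg, "run1")   # simulates the fixture, then runs everything
```

```
[simulate] generating fixture (seed 1)
[inputs] reading image, imzML and annotations
[features] computing 2-scale feature stack
[classifier] training pixel classifier
[classifier] train accuracy 1.000
[classifier] 28 detections after post-processing
[register] fitting and refining the coregistration
[register] refinement score 0.923
[rois] transferring labels and building FC/PAT/PC ROI sets
[rois] spots: FC=313 PAT=239 PC=213
[spectra] normalising and picking peaks per ROI type
[compare] interferent panel, PCA and ROC per ROI type
[write] writing results to run1
```

```r
res$model
```

```
Pixel classifier: 16 features x 2 classes (32 parameters, no bias)
  classes: cell_rich, non_cell_rich
  train accuracy: 1.000 on 1470 pixels
```

```r
res$rois$PC
```

```
ROI set [PC]: 213 spots in 4 labels
   FA FVPTC NIFTP   PTC 
   54    52    52    55 
```

```r
head(res$peak_lists$PC, 5)
```

```
Peak list: 5 peaks (S/N >= 6, rel. intensity >= 0.3%)
        mz intensity       snr
1 839.0809 20.240827 1899.3138
2 842.5090  7.033393  659.3883
3 845.0909 20.888968 1957.0129
4 855.0500 21.104817 1972.0302
5 861.0590 20.891434 1948.9980
```

```r
res$summary$spot_counts
#>  FC PAT  PC 
#> 313 239 213
res$summary$discriminatory_counts
#>  FC PAT  PC 
#>   9  11  12
round(res$summary$interferent_percent_change, 2)
#>    FC   PAT 
#> -1.92 -6.30
```

The pixel-classifier ROIs are the smallest (213 < 239 < 313 spots), carry
*less* interferent signal than either conventional ROI (negative percent
change), and expose the *most* discriminatory m/z features between the four
diagnoses (12 > 11 > 9) — including all eight peptides planted as
diagnosis-specific by the fixture generator.

`run_pipeline()` writes `roi_spots.csv`, per-type `peaks_*.csv` and
`roc_*.csv`, `interferent_table.csv`, the serialized classifier and
transform, and a provenance manifest with input MD5 checksums.

The same pipeline runs from the command line:

```sh
Rscript inst/cli/morphomsi.R simulate --seed 1 --out fixture/
Rscript inst/cli/morphomsi.R run --seed 1 --out run1/
```

To run on real inputs instead of the simulated fixture, set
`simulate = FALSE` in the config (or YAML) and point `paths$image`,
`paths$imzml`, `paths$training`, `paths$pathologist` (GeoJSON with QuPath
`classification` properties) and `paths$control_points` at your files.

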