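# polarMSI

Polarimetry-guided targeted mass spectrometry of tissue, as a reusable,
fully testable R pipeline.

Targeted tissue MS — DESI-MS raster imaging of thin slices, hand-held PIRL
laser point sampling of thick specimens — is accurate but slow, so a fast,
non-destructive survey is needed to decide where to acquire. Wide-field
Mueller-matrix polarimetry provides that survey: in a breast-tumour
xenograft model, viable cancer is weakly depolarizing (depolarization
histograms peaking near 20%), necrotic cancer more so (near 35%), and
healthy muscle more than both, so depolarization contrast can steer MS
acquisition to the informative regions of the *same* tissue surface.
polarMSI implements the whole chain and quantifies how well the two
modalities agree.

## What the package computes

* **Mueller polarimetry** — forward simulation of polarization-resolved
  image stacks (default: 6 generator × 4 analyzer states, 24 frames; frame
  value ½ aᵀMg), per-pixel inversion of `W vec(M) = I` by pseudo-inverse,
  and the Lu–Chipman polar decomposition `M = M_Δ M_R M_D` with net
  depolarization `Δ = 1 − |tr m_Δ|/3`, diattenuation and retardance.
  Reflection-mode maps use the complementary *surviving polarization*
  `1 − Δ`.
* **Tissue phantom** — ground-truth label maps (necrotic core, viable rim,
  muscle band) on the 1.7 cm × 1.7 cm / 17 µm-per-pixel field of view,
  class-wise depolarization rendering, and serial-section morphology drift
  calibrated to the 1–1.5 mm internal-border mismatch seen between
  consecutive sections.
* **MS simulation** — DESI-MS rasters (100 µm/s stage, 1 s integration,
  100 µm pixels) with class-specific lipid marker chemistry (m/z 391.25
  viable, 572.48 necrotic, 281.25/303.23/331.26 breast lipids), PIRL
  point-sampling spectra for breast tissue classes and a mouse-organ panel,
  and 20 ppm peak matching.
* **Guidance** — slide-corner rigid registration (2-D Procrustes, no
  scale), automatic ROI proposal from depolarization contrast (2-/3-class
  Otsu with a hyper-depolarizing healthy-tissue exclusion), raster
  scan-time model and speed-up: the reference 8-ROI set (six 1 mm², two
  4 mm²) scans 1400 pixels against 28 900 for the full field — 20.6× faster.
* **Concordance** — TIC normalization, ion images, per-ROI marker means
  over all pixels (5–6× necrotic/viable fold in necrotic ROIs, 3–4× the
  other way in viable ROIs), detected-pixel intensity histograms and
  depolarization histograms (2.5-point bins), concordant/discordant
  verdicts.
* **Chemometrics** — peak alignment (20 ppm), >80%-missing filter, PPCA
  imputation (EM), IQR filter, sum normalization, Pareto scaling, and
  NIPALS PLS-DA with class prediction by argmax.

## Worked example

```r
library(polarMSI)
res <- run_workflow(run_config(seed = 1))
print(res$summary)
#> Polarimetry-MS concordance: 8 ROIs, 100% concordant
#>  hypothesis depol_mean_pct depol_class dominant_marker fold    verdict
#>    necrotic           35.2    necrotic        necrotic 5.18 concordant
#>    necrotic           34.0    necrotic        necrotic 3.85 concordant
#>    necrotic           35.2    necrotic        necrotic 4.48 concordant
#>      viable           21.1      viable          viable 2.91 concordant
#>      viable           19.7      viable          viable 3.77 concordant
#>      viable           19.5      viable          viable 3.32 concordant
#>      border           27.2      border           mixed 1.25 concordant
#>      border           27.4      border           mixed 1.08 concordant
res$speedup
#> [1] 20.64286
```

The run generates a phantom slice, simulates the 24-frame polarimetric
acquisition with 1% noise, reconstructs per-pixel Mueller matrices,
extracts the depolarization map, proposes 8 targeted ROIs, simulates DESI
rasters inside them and scores polarimetry–MS agreement. Each row is one
ROI: its polarimetric class call (from the mean depolarization, in
percent), the dominant MS marker, and the all-pixel marker fold change —
necrotic ROIs show the necrosis marker m/z 572.48 at a 4–5× higher mean
relative abundance than the viable marker m/z 391.25, viable ROIs the
reverse at 3–4×, and border ROIs a mixed population. The 14 mm² targeted
plan needs 1400 s of stage time against 28 900 s for the untargeted full
field.

Organ classification from point-sampling spectra:

```r
specs <- lapply(1:6, function(r) simulate_pirl("liver", 10, seed = r))
specs <- c(specs, lapply(1:6, function(r) simulate_pirl("brain", 10, seed = 10 + r)))
tab <- preprocess_spectra(specs, rep(c("liver", "brain"), each = 6))
fit <- plsda(tab, n_components = 2)
predict(fit, tab)$class
#>  [1] liver liver liver liver liver liver brain brain brain brain brain brain
```

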