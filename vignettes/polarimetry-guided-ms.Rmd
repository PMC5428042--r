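---
title: "Polarimetry-guided mass spectrometry: models, phantom design and numerical choices"
author: "polarMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polarimetry-guided mass spectrometry: models, phantom design and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarMSI)
```

## The problem

Targeted mass spectrometry of tissue — DESI-MS raster imaging of thin
slices, or hand-held PIRL laser point sampling of thick specimens — is slow
and destructive, so a fast wide-field survey modality is needed to decide
*where* to point the mass spectrometer. Wide-field Mueller-matrix
polarimetry provides such a survey: depolarization contrast separates
viable tumour (weakly depolarizing), necrotic tumour (more depolarizing)
and healthy muscle (most depolarizing of the three) in a breast-tumour
xenograft model, and because the polarimetric survey is non-destructive the
*same* tissue surface can be used for guidance, MS acquisition and
follow-up histology. polarMSI implements this workflow end to end as
testable code, with a synthetic tissue phantom standing in for raw
instrument data, which is not publicly deposited for this system.

## Polarimetric model

A pixel's optical response is a 4×4 real Mueller matrix $M$ acting on
Stokes vectors. The instrument model pairs a polarization state generator
(PSG) and analyzer (PSA): with generator state $g_k$ and analyzer state
$a_k$ (both unit-intensity Stokes vectors), the detected frame value is

$$ I_k = \tfrac12\, a_k^T M\, g_k , $$

the $\tfrac12$ being the ideal-polarizer detection factor. Stacking the
$K$ measurements gives $I = W\,\mathrm{vec}(M)$ with
$W_{k\cdot} = \tfrac12 (g_k \otimes a_k)^T$. The default scheme pairs six
generator states (H, V, ±45°, R, L) with four analyzer states (H, V, +45°,
R): $K = 24$ frames, $\mathrm{rank}(W) = 16$, condition number ≈ 5.6.
Reconstruction solves the per-pixel least-squares problem through the
Moore–Penrose pseudo-inverse of $W$; with 24 independent measurements of 16
unknowns the inversion is overdetermined and noise-averaging. The published
instrument does not list its 24 PSG/PSA combinations, so the canonical
6 × 4 scheme is the default and any scheme with $\mathrm{rank}(W) = 16$ can
be configured; a real instrument's eigenvalue calibration is out of scope
and an exact known instrument model is used instead.

Depolarization is extracted by the Lu–Chipman polar decomposition
$M = M_\Delta M_R M_D$. The diattenuation vector $\vec d$ is the first row
of the normalized matrix; after dividing out $M_D$, the depolarizer block
$m_\Delta$ is the signed symmetric square root of $m' m'^T$ (sign from
$\det m'$, the standard resolution of the sign ambiguity), and

$$ \Delta = 1 - \tfrac13\,\lvert \operatorname{tr} m_\Delta \rvert
\in [0, 1], $$

the net depolarization, reported as a percentage. Retardance is
$R = \arccos(\operatorname{tr}(M_R)/2 - 1) \in [0, \pi]$. Singular
diattenuators ($D \to 1$) fall back to a pseudo-inverse and flag the
result. For thick-tissue reflection imaging the display convention is
*surviving polarization* $1 - \Delta$: regions of low depolarization in
thin-sample transmission appear as regions of low surviving polarization in
reflection, so the same contrast ordering is preserved with the metric
complemented.

## The tissue phantom

`make_label_map()` draws a tumour-infiltrated slice: an elliptical tumour
with a necrotic core and viable rim inside a muscle band, on a 1000 × 1000
px canvas at 17 µm/px (the 1.7 cm × 1.7 cm polarimetry field of view).
Region boundaries get a seeded low-order harmonic wobble so seeds produce
distinct morphologies. Class depolarizations are truncated normals:

| class    | mean Δ | sd   | rationale |
|----------|--------|------|-----------|
| viable   | 0.20   | 0.05 | histogram peak of viable-cancer regions |
| necrotic | 0.35   | 0.05 | histogram peak of necrotic regions |
| muscle   | 0.50   | 0.05 | free calibration satisfying the ordering muscle > necrotic > viable |
| background | —    | —    | invalid pixels |

The viable and necrotic means are the published histogram peaks; no
numeric value is published for muscle, only the ordering, so 0.50 is a
calibration, as is the common 0.05 standard deviation (chosen so the
reconstructed per-class histograms are clearly peaked at 2.5-point binning
while the classes still overlap pixel-wise, as real tissue does). Phantom
pixels are pure isotropic depolarizers `diag(1, 1-Δ, 1-Δ, 1-Δ)`; the
guidance signal in this workflow is depolarization only, so retardance and
diattenuation are left to the decomposition tests rather than the phantom.
Reflection rendering converts to the surviving-polarization convention,
compresses contrast about the tissue mean (factor 0.5) and blurs with a
100 µm Gaussian — a display-level stand-in for thick-tissue degradation,
not a radiative-transfer model.

### Serial-section drift

Consecutive sections tens of micrometres apart show internal-border
mismatches of 1–1.5 mm even after optimized rigid-body overlay of the outer
tissue border. `serial_drift()` emulates this with a displacement field
composed of (a) coherent internal slip along two orthogonal random axes
through the section center — each axis splits the section into halves
shifting in opposite directions with a smooth `tanh` transition — plus (b)
a small smooth random roughness field. The slip is antisymmetric, hence
invisible to rigid alignment, and the field is tapered to zero toward the
canvas edge so the section outline stays put (and on the slide) while
internal morphology drifts.

Because the reference figure is a *residual after rigid overlay*, and
because the nearest-boundary metric saturates below the raw displacement
once contours cross, the nominal `boundary_shift_mean_um` (default 1250 µm,
the midpoint of the 1–1.5 mm range) is imposed by construction: the field
amplitude is solved by a short fixed-point iteration until the
rigid-aligned mean boundary mismatch of the viable mask reaches the nominal
value, backing off whenever a trial amplitude would push tissue off the
canvas. Across seeds the default phantom lands at ≈ 1.2–1.3 mm.

## MS simulation

DESI-MS rasters follow the published acquisition geometry: 100 µm/s stage,
1 s spectral integration, hence 100 µm pixels; spectra are centroided peak
lists in m/z 200–1000. Per raster pixel the majority tissue class selects a
marker profile; each marker ion is detected with a presence probability and
its relative intensity (fraction of total ion current, TIC) is drawn from a
Beta distribution parameterized by mode and concentration; background ions
fill the remaining TIC; observed m/z values get 5 ppm Gaussian jitter, well
inside the 20 ppm matching tolerance. Default marker profiles:

| class | m/z | presence | TIC-fraction mode | concentration |
|-------|------|---------|------|------|
| necrotic | 572.48 | 0.95 | 0.45 | 30 (wide) |
| necrotic | 391.25 | 0.55 | 0.15 | 200 (tight) |
| viable | 391.25 | 0.95 | 0.35 | 100 |
| viable | 572.48 | 0.70 | 0.13 | 200 (tight) |

(plus 303.23 / 281.25 / 331.26 breast lipids in both cancer classes, 303.23
rarer in muscle). This single parameterization reconciles two published
observations at once: detected-pixel histograms peak at ≈ 0.45 / 0.35 for
the dominant markers and ≈ 0.15 / 0.13 for the recessive ones, while
*all-pixel* mean abundances differ 5–6 fold (necrotic ROIs) and 3–4 fold
(viable ROIs) — means include undetected pixels as zeros, so a less
populous tight distribution yields a low mean. The "relative ion intensity"
throughout is peak intensity divided by per-spectrum TIC, which makes every
fold change invariant to global intensity rescaling.

PIRL point-sampling spectra are Poisson: expected counts are `rate ×
duration`, so intensities scale linearly with the 5–10 s sampling times.
Mouse organs share a fatty-acid/phospholipid panel whose *relative
intensity pattern* is organ-characteristic (a rotated intensity profile
over 12 shared phospholipids), topped by one or two organ-unique m/z
values. Identity is thus encoded mostly quantitatively — as in real lipid
profiles — rather than purely by presence/absence, which matters because
features observed in only one class carry no cross-class covariance for
imputation to exploit.

## Guidance and registration

Slide-corner fiducials tie the optical/polarimetry frame to the MS stage
via a 2-D orthogonal Procrustes fit without scaling (both frames have known
pixel sizes, so "rigid body methods" means rotation + translation only).
Coordinates are stage micrometres, origin at the top-left fiducial, x
rightward, y downward, pixel centers at (i − ½) · pitch.

ROI proposal thresholds the *smoothed* depolarization map (Gaussian σ = 2
px averages the pixel noise so class populations separate). Because
healthy tissue is *more* depolarizing than necrotic tumour, the histogram
is trimodal and a naive "necrotic = highest depolarization" rule would
target muscle; the implementation therefore fits both 2- and 3-class Otsu
splits and keeps the 3-class solution when each class holds ≥ 5% of pixels
and the between-class variance improves by more than 5% (measured: bimodal
maps improve ≤ 3%, trimodal ≥ 7%). Necrotic ROIs then seed in the middle
band, viable below the first split, and border ROIs on the high-gradient
band around the viable/necrotic split — required, via a morphological
opening that removes thin smoothing ramps, to have genuine viable and
necrotic regions on both sides. ROIs are placed greedily (largest first),
non-overlapping, with ≥ 70% band purity for class ROIs. The default
request is the published configuration: six 1 mm² plus two 4 mm² ROIs,
14 mm² total, which at 100 µm pitch and 1 s per pixel gives 1400 s versus
28 900 s for the full 1.7 cm field — a 20.6-fold reduction, matching the
published "> 20×" claim. The published "~8 minutes" for the same 14 mm² is
inconsistent with its own raster parameters (14 mm² at 1 s per 100 µm pixel
is 1400 s ≈ 23 min); the pixel-count model is used and the "> 20×" bound is
the quantitative anchor.

Boundary mismatch between two masks is the symmetric mean nearest-neighbour
distance between their contour point sets after a rigid pre-alignment from
mask centroids and principal axes; mask pixels clipped by the canvas edge
contribute no contour.

## Chemometrics

Point-sampling spectra go through, in order: peak alignment (greedy
single-linkage along m/z, 20 ppm merge radius, intensity-weighted cluster
centers), removal of features with > 80% missing values (strict
inequality), PPCA imputation, IQR filtering, per-spectrum sum
normalization, and Pareto scaling (center, divide by √sd — the scaled
variance equals the original sd). PPCA is an EM iteration on the completed
matrix: re-estimate loadings and noise variance by SVD, replace missing
cells with the posterior-mean reconstruction, converge when the relative
log-likelihood change or the relative imputation update drops below 1e-6
(cap 1000 iterations, non-convergence flagged). Initialization is
deterministic (column-mean fill), so the pipeline needs no seed. The
latent dimension defaults to min(5, samples − 1); the IQR drop fraction
defaults to 0.25 and is configurable, since the web tool the original
analysis used does not document its adaptive rule.

Classification is PLS-DA: NIPALS PLS2 against the one-hot class matrix,
prediction by argmax of the predicted class responses, no threshold.
Successive score vectors are orthogonal by construction, and on small
instances the first weight vector equals the dominant right singular
vector of the class–feature cross-covariance, which the tests verify
against a brute-force SVD oracle and against an independent PLS-DA
implementation.

## Problem sizes and numerical choices

The test-suite and acceptance computations use these sizes, chosen so each
estimate is stable at its binning:

* depolarization round trips: 4 mm² single-class regions, 118 × 118 px at
  17 µm (≈ 14 000 pixels per histogram);
* end-to-end guided runs: the full 1.7 cm phantom with the polarimetric
  round trip at 4× binning (68 µm/px) — ROI guidance needs millimetre-scale
  contrast, not single-pixel resolution — while DESI simulation samples the
  full-resolution label map;
* DESI marker statistics: 64 × 64 px rasters at 100 µm (≈ 4100 spectra);
* drift: the full 1000 × 1000 phantom.

Histogram conventions: depolarization in percent with 2.5-point bins,
relative intensity with 0.025 bins, bins anchored at zero, mode = center of
the maximal bin, ties to the lower bin; detected-pixel histograms exclude
zeros while means run over all pixels; border-ROI centers are reported as
histogram means, since a 50/50 border region is bimodal and a mode would
arbitrarily pick one shoulder.

## What the phantom does and does not show

Passing the synthetic round trips demonstrates that the pipeline's inverse
operations recover what its forward models generate at realistic noise, and
that the guidance logic makes the correct targeting decisions under the
published contrast. It does not validate the biology: the phantom has no
spatial texture within classes, no retardance or diattenuation in tissue,
no chemical noise structure (isotopes, adducts, matrix effects), ideal
instrument calibration, and its reflection mode is a contrast convention
rather than a scattering model. Real-tissue performance therefore cannot be
inferred from these tests beyond the consistency of the method chain
itself.
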