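---
title: "Simulated spectral-domain OCT biometry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated spectral-domain OCT biometry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boct)
```

## The measurement problem

Ocular biometry estimates the axial dimensions of the eye — axial length
(AXL), anterior chamber depth (ACD), lens thickness (LT) and central corneal
thickness (CCT) — that drive intraocular-lens power calculation. A
spectral-domain OCT retinal scanner images only a shallow depth range
(here 2.5 mm) at a time, far less than a whole eye, so biometry on such a
device works by *relocating* the imaged depth window: the zero-delay
reference (C-gate) is shifted along the measurement axis so that four
windows, each 3 mm wide and 2.5 mm deep, successively contain (1) both
corneal surfaces, (2) the anterior lens surface, (3) the posterior lens
surface — the lens is thicker than one window, so its two surfaces are split
across windows 2 and 3 — and (4) the retina. The five specular boundaries
identified in those windows, placed on a common apex-referenced optical
axis via the known gate offsets, give the optical spans of the ocular
segments; dividing by group refractive indices converts them to geometric
distances.

`boct` implements this measurement chain end to end against a synthetic
ground truth (an *eye phantom*), plus the statistics framework used to
validate such an instrument: within-subject SD (Sw), test-retest
repeatability (TRT), coefficient of variation (CoV), one-way intraclass
correlation (ICC), Bland–Altman limits of agreement and paired t-tests.

## The eye phantom

`build_phantom()` stacks four media (cornea, aqueous, lens, vitreous) with
per-medium group indices and anterior-interface reflectivities, a retina
model and an optional lens opacity. The default phantom is a mean healthy
adult eye: AXL 23.93 mm, ACD 3.59 mm, LT 4.02 mm, CCT 555.44 µm, with the
aqueous and vitreous thicknesses derived so the dimensions close exactly
(`AXL = CCT + aqueous + LT + vitreous`). Conventions:

* **ACD** is referenced to the anterior corneal surface (epithelium), i.e.
  it includes CCT. Devices differ here; the epithelium reference keeps
  `ACD = CCT + aqueous depth` additive and is stated explicitly because the
  alternative (endothelium) reference differs by exactly CCT.
* **AXL** ends at the RPE, the brightest posterior reflector, as in optical
  biometry generally. When the retina model elevates the RPE (drusenoid RPE
  detachment), the *correct* measurement target becomes Bruch's membrane,
  which stays at the nominal depth; `geometric_dimensions()` reports both
  so the manual-correction workflow can be verified.
* Depths are positive millimetres from the corneal apex, continuous at the
  phantom level; pixelization happens only in the simulator.

Group indices at 840 nm are not measurable from the instrument itself and
are set to standard literature values (cornea 1.387, aqueous 1.342, lens
1.408, vitreous 1.341, averaged whole-eye 1.3549); all are configurable,
and `sim_config(device_mode = TRUE)` reproduces the single-averaged-index
conversion for AXL that a device without per-segment knowledge would apply.

Pathology models, each reduced to the feature that matters for biometry:

* **Lens opacity** (`pathology$opacity_*`): multiplies the amplitude of
  every reflector strictly posterior to the opacity plane by
  `1 - attenuation` within its lateral extent — the "shadow" a cataract
  casts on the retinal signal. A reflector *at* the opacity plane (the
  posterior capsule under a subcapsular opacity) is not shaded.
* **RPE elevation**: moves the RPE reflector anteriorly while Bruch's
  membrane (a weak reflector, default 0.12 vs 0.55 relative amplitude)
  stays put.
* **Retinal detachment**: adds a detached-retina reflector anterior to the
  RPE and halves the RPE amplitude (sub-retinal fluid scattering).

## The A-scan simulator

`simulate_spectrum()` works in the spectral-fringe domain: each reflector
within reach of the gate contributes a cosine fringe whose frequency maps
to its depth below the gate and whose amplitude is
reflectivity × shadow × roll-off, with additive Gaussian spectral noise.
`reconstruct_ascan()` applies a Hann window, Fourier transforms, and takes
the magnitude envelope. Speckle is applied in the envelope domain as
mean-one multiplicative Rayleigh-like noise rather than simulating the
full complex field — sufficient for specular-boundary detection at a
fraction of the cost.

Numerical choices worth stating:

* 2048 spectral samples give 1024 usable depth pixels; at the 2.4 µm pixel
  this is 2.458 mm, marginally less than the nominal 2.5 mm window. The
  A-scan length is therefore `min(floor(window_depth / pixel), N/2)`
  pixels, and the gate solver keeps targets at least `gate_margin_mm`
  (default 0.3 mm) from both window edges, so the shortfall never clips a
  target boundary.
* The Hann main lobe has an on-bin amplitude FWHM of 2.0 pixels = 4.8 µm,
  within the 5 µm nominal axial resolution; off-bin scalloping can widen a
  single peak by a few percent.
* Sensitivity roll-off is Gaussian in window depth with a configurable
  6 dB depth (default 1.8 mm); spectrometer roll-off curves are
  device-specific and unpublished, so this is a generic shape.
* Gate offsets are *apex-referenced* optical depths and may be negative
  (zero-delay above the cornea), which is how window 1 keeps the corneal
  surfaces away from the DC bin.
* Every shot draws an independent axial alignment jitter per window
  (default SD 5 µm). Spans composed *within* one window (CCT) are immune
  to it; spans across windows (ACD, LT, AXL) inherit √2 × 5 µm per-shot
  noise, which is what puts the series SD of AXL at the observed
  repeatability scale (≈5–7 µm per shot, ≈1–2 µm after averaging 20
  shots).

All randomness flows through explicit seeds (`withr::with_seed`); the same
seed gives bit-identical acquisitions.

## Boundary segmentation

Per A-scan, envelope peaks are detected above an adaptive threshold
(median + k·MAD of the envelope, default k = 6) with a relative floor of
10% of the envelope maximum (suppresses Hann sidelobes, which sit near 3%,
on noiseless data), refined to sub-pixel position by three-point parabolic
interpolation. Peak-to-boundary assignment uses order statistics rather
than model fitting — the interfaces are specular and well separated:
window 1 takes the two dominant peaks as cornea front/back; window 2 the
shallowest peak (lens front); windows 3 and 4 the deepest *strong* peak
(≥25% of the tallest peak), which makes auto-detection stop at the RPE
rather than the weak Bruch reflector. Detections are pooled across the
central 1 mm of A-scans by median; a boundary found in fewer than half of
them is reported absent with confidence 0 — the flag that calls for manual
correction. Confidence is a saturating function of the peak-to-threshold
ratio, so a retinal peak barely above threshold under a dense cataract is
flagged low-confidence rather than silently trusted.

`apply_manual_override()` is the clinician path: edits are all-or-nothing,
must preserve anatomical ordering, and are marked `source = "manual"`;
recomputing biometry from the edited set propagates the correction (e.g.
moving the posterior boundary from an elevated RPE to Bruch's membrane).

## Biometry composition and conversion

Each shot contributes the optical spans CCT (window 1), ACD (cornea front →
lens front across windows 1–2), LT (windows 2–3) and AXL (windows 1–4).
Because all five boundaries are available, conversion is per segment:
`geometric = Σ optical_segment / n_segment`, the exact inverse of the
optical path integral; `device_mode` instead divides the whole AXL span by
the averaged eye index. Shots are filtered per orientation by a modified
z-score rule (reject when `|x − median| / (1.4826·MAD) > 2.5`; nothing is
rejected when MAD = 0), a robust, scale-free reading of "outliers are
rejected"; if fewer than 5 of 10 shots survive, the parameter fails for
that orientation, and a parameter fails outright only when both
orientations fail. Horizontal and vertical series are pooled *after*
per-orientation rejection. Results print at 2 decimals with full precision
retained internally.

The glass-block accuracy check mirrors instrument calibration against a
reference block: the device value (optical / n_eye) rescaled by
n_eye / n_glass gives the true glass thickness, compared against a
coordinate-machine reference; with the shipped N-BK7 group index (1.527 at
840 nm) the bookkeeping reproduces a 0.0024 mm accuracy delta from the
corrected 29.9964 vs reference 29.9940 mm thicknesses.

## Precision and agreement statistics

`within_subject_sd()` is √(residual mean square) of the one-way ANOVA with
subject as the factor; `trt()` is exactly 2.77·Sw (2.77 ≈ 1.96√2, the 95%
interval for a difference of two measurements); `cov_percent()` is
100·Sw/mean. `icc_oneway()` is the one-way random-effects single-measure
ICC, `(MSB − MSW) / (MSB + (k−1)·MSW)` — chosen to be model-consistent
with Sw's one-way ANOVA; for unbalanced designs k is the harmonic-mean
replicate count. `bland_altman()` reports mean difference, SD, LoA with
the 1.96 multiplier exactly (not a small-sample t multiplier — LoA are a
descriptive interval here), a t-based 95% CI of the mean difference, the
paired t-test (degenerate zero-variance differences give p = 1 when the
mean difference is 0) and the ICC of the paired values. Interobserver
reproducibility uses each observer's *first* reading per subject, with
observers as the replicate dimension (`first_readings_study()`).

## The synthetic study runners

`run_repeatability_study()` simulates the subjects × observers × replicates
design and `run_agreement_study()` the paired two-device design. The
default cohorts are drawn at the validation-study scale: healthy truth
AXL ~ N(23.93, 0.80) mm, ACD N(3.59, 0.28), LT N(4.02, 0.22), CCT
N(555.44, 26.56) µm, with replicate noise AXL/ACD 0.01 mm, LT 0.02 mm,
CCT 2 µm — the instrument's repeatability scale, which in the simulator
emerges from jitter + speckle + quantization. Two modes:

* `mode = "gaussian"` (default): replicate = truth + Gaussian noise at
  `within_sd`. This is the *measurement-level* model — `within_sd` stands
  for everything a full measurement with realignment contributes — and is
  what makes 50 × 3 designs instantaneous.
* `mode = "simulate"`: every replicate runs the full
  `measure_biometry()` pipeline on a phantom built from the subject's
  truth (used with small cohorts; about 3 s per measurement).

With the study-scale variance components (between-SD 0.80 mm, within-SD
0.01 mm) the AXL ICC is ≈ 0.99984 and rounds to 1.000 at three decimals —
the headline repeatability figure — robust to seed choice because the
sampling SD of the ICC estimate at n = 50, k = 3 is far below the rounding
slack.

```{r, eval = FALSE}
pr <- study_protocol(n_subjects = 50, observers = 2, replicates = 3, seed = 1)
res <- run_repeatability_study(pr)
res$intraobserver$observer_1$axl
```

## What the simulation does and does not show

The phantom reproduces the *axial* signal structure biometry relies on:
bright specular boundaries, depth roll-off, opacity shadows, RPE/Bruch
geometry, alignment jitter. Passing tests therefore demonstrate that the
measurement chain — gating, segmentation, outlier rejection, index
conversion, statistics — is internally correct and recovers known truth at
the instrument's precision scale. They do not validate against real
tissue: no curvature or off-axis geometry, no dispersion or
complex-conjugate artifacts, no fixation drift within an A-scan, speckle
without spatial correlation, and literature (not measured) group indices.
Clinical failure rates and device-difference magnitudes measured on real
eyes are likewise outside what synthetic cohorts can reproduce; the study
runners reproduce the *statistical machinery* on matched scales, not the
patients.

## Problem sizes used in the shipped tests

Tests run noiseless boundary-recovery grids over AXL 19–34 mm, a 25-phantom
full-pipeline recovery sweep at 10 shots × 2 orientations each, and
measurement-level studies at the published design sizes (50 × 2 × 3
repeatability; 164 and 115-eye agreement). These sizes keep the whole suite
under a couple of minutes on one core while leaving the statistical checks
comfortably powered.
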