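---
title: "Detecting interproximal caries in SWIR and CP-OCT images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interproximal caries in SWIR and CP-OCT images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swircaries)
```

## The problem

Dental enamel is highly transparent at short-wavelength infrared (SWIR)
wavelengths (roughly 1000–2300 nm), which makes it possible to image caries
lesions between adjacent teeth (interproximal, Class II lesions) without
ionizing radiation. Demineralized enamel scatters SWIR light much more
strongly than sound enamel, so a lesion appears *bright* against dark sound
enamel in reflectance imaging (SWIR-R), and *dark* against bright enamel
when the tooth is transilluminated from the gum line (occlusal
transillumination, SWIR-OT) or through the contact (proximal
transillumination, SWIR-PT). Cross-polarization optical coherence tomography
(CP-OCT) provides depth-resolved cross-sections (b-scans) in which a lesion
shows up as elevated subsurface reflectivity.

This package implements the complete analysis chain used to compare these
modalities against radiography: contrast-map segmentation of SWIR frames,
lesion metrics (area, mean contrast, penetration depth), a cylindrical-ruler
depth measurement for CP-OCT b-scans with refractive-index correction,
radiographic lesion contrast with cross-modality scale transfer, and the
detection-rate / repeated-measures statistics that summarize a study. A
synthetic phantom generator with exact ground truth stands in for clinical
images, so that every stage is testable end to end.

## SWIR contrast model and segmentation

Raw frames are converted to dimensionless contrast maps against a manually
selected sound-enamel reference. With $I_t$ the target pixel and $I_s$ the
mean intensity of the sound region adjacent to the contact:

* reflectance: $C = (I_t - I_s) / I_t$ (lesions bright, $C > 0$),
* transillumination (both OT and PT): $C = (I_s - I_t) / I_s$ (lesions
  dark, $C > 0$).

Both transforms are bounded above by 1 and may be negative. Reflectance
pixels with $I_t = 0$ have no finite contrast; they are flagged and never
enter a mask. The segmentation is deliberately *semi-automatic*: the sound
region and the contact ROI are inputs, not detected — that mirrors how these
measurements are made in practice, and automatic ROI placement is out of
scope.

A contrast of 0.1 is the reference threshold for a positive detection:
pixels with contrast *lower* than 0.1 are removed, so a pixel exactly at the
threshold is kept (`threshold_mask()` uses `>=`). Connected components of
the binary mask are labeled and only components adjoining the proximal
contact ROI are kept as the lesion; this single rule is what discards
specular highlights in reflectance frames and direct-light bleed or dark
background in transillumination frames, which are bright/dark areas *away*
from the contact. Design choices here:

* **Connectivity is 8-connected** for both component labeling and the
  "adjoins the contact" test, so a diagonal touch through a thin contact
  band counts. It is configurable (`connectivity = 4`).
* **Multiple adjoining components are merged** into one lesion for metrics;
  one lesion is reported per surface.
* **$i_s$ is the arithmetic mean** over the sound ROI; a median is
  available via `stat = "median"` for robustness against stray pixels.

For a detected lesion, `lesion_metrics()` reports the pixel and physical
area and the mean contrast over the mask. **Lesion depth on a 2-D
projection has no canonical definition**; this package defines it as the
maximal extent of the segmented component measured perpendicular to the
contact line (penetration away from the proximal surface), in pixels times
the calibrated scale. The contact line direction is taken as the principal
axis of the contact ROI pixels. This convention is applied identically to
all SWIR modalities so that cross-method comparisons remain well defined;
it is a stated convention of this package, not a universal standard.

Pixel-to-mm calibration uses a reference target
(`calibrate_px_to_mm()`: scale = known length / measured pixels).
Radiographs have no target; their scale is transferred from a calibrated
SWIR image through the matched mesial–distal span of the same tooth
(`transfer_scale()`), which is exact under the ratio model and transitive
to rounding error.

## Radiographic contrast

Radiographic lesions are radiolucent (darker), so contrast is
$(I_s - I_L)/I_s$ with $I_L$ the mean over the examiner-drawn lesion ROI
and $I_s$ a sound region *directly above or below* it — same column band,
hence comparable enamel thickness. The package operationalizes "directly
above or below" as at least 80% column overlap between the two ROIs
(configurable) and warns otherwise. Because digitized film can arrive with
inverted polarity, a `polarity = "inverted"` flag computes the contrast on
the inverted convention; negative contrast under the assumed polarity is
flagged as non-lesion-like rather than silently accepted. There is no
contrast threshold for radiographic detection — detection calls on
radiographs are examiner labels, and the package keeps them that way.

## CP-OCT depth measurement

B-scans store rows as axial *optical* distance. The measurement chain is:

1. **Despeckle** with a kernel-3 median filter. Border pixels use the
   median of the in-image (clipped) part of the window, so no synthetic
   padding values are invented; kernel 1 is the identity.
2. **Surface fit**: in each column of a ±10 px lateral window, the surface
   is the first axial sample reaching half the column maximum; a least
   squares line through those points gives the surface, and the ruler
   starts on it, pointing along the inward normal. The ruler origin is the
   *detected surface* (not the first minimum) — the starting point is
   otherwise unspecified, and the surface is the reproducible landmark.
3. **Cylindrical ruler**: the profile value at each 10 µm step along the
   axis is the mean of bilinearly interpolated intensities over a disk of
   100 µm diameter centred on the axis ("100 µm disk" is read as a
   *diameter*; configurable). In the 2-D scan plane the disk reduces to a
   transverse segment of that width, sampled symmetrically — on a locally
   linear intensity field the symmetric weights cancel and the centre value
   is returned, which is the property the tests pin down.
4. **Depth**: the two lowest *local minima* of the lightly smoothed profile
   (moving average, 3 samples) bracket the elevated-reflectivity lesion
   band; depth is the axial distance between them divided by the
   refractive index. A "difference between the two lowest intensities"
   only has length units when read as the distance between the two
   lowest-intensity minima, and that reading is adopted as the central
   interpretive decision of this module.

Two guards make the minima-pair rule safe. Enamel birefringence produces
periodic intensity banding with depth, so a *prominence* check requires the
profile to rise, between the two chosen minima, by at least 10% of the
profile's dynamic range above both minima — banding maxima fail this,
lesions pass easily. Expressing the prominence as a fraction of the range
makes the whole measurement invariant to global intensity scaling. Second,
local minima on plateaus are collapsed to the plateau midpoint, and the
chosen minima are then refined to the argmin of the *unsmoothed* profile
within half a smoothing window — smoothing a sharp dip otherwise biases its
location by up to half the window.

Optical-to-physical conversion divides by the enamel refractive index
(default 1.6): a 7 mm axial scan range in air reaches only
$7 / 1.6 = 4.4$ mm into enamel (`max_physical_range()`), and the same
factor converts inter-minima distances into physical lesion depths. Whether
a reported depth should be index-corrected at all is exposed as
`correct_index`; the package corrects by default.

## Detection statistics

`detection_table()` holds one row per contact, surface (restored/opposing),
and method. Rates are fractions of surfaces with a positive call, with
missing calls excluded from numerator and denominator, reported to two
decimals rounded half-up. Rate comparisons against radiography use the
two-sided Fisher exact test (`stats::fisher.test`; the test suite verifies
it against exhaustive enumeration of all tables with the observed margins).

Lesion contrast and depth are compared with a one-way repeated-measures
ANOVA computed directly from the sum-of-squares decomposition
(subject = contact-surface), after removing every subject with a missing
value in any compared method — the complete-case convention. Post-hoc
pairwise comparisons use the Tukey studentized range on the
repeated-measures error term (`ptukey` with $q = |\bar y_i - \bar y_j| /
\sqrt{MS_e/n}$); Bonferroni-adjusted paired contrasts are available by
flag. The post-hoc correction is a stated assumption of this package:
Tukey is the default repeated-measures multiple-comparison procedure of the
software this analysis style comes from. A mixed-effects model
(`lme4::lmer` + emmeans), which tolerates missing values, is provided as a
cross-check path (`mixed_effects_check()`), not as the primary computation.

The compact letter display assigns letters to the maximal cliques of the
non-significance graph (methods share a letter iff all pairwise $p >
\alpha$ within the set), ordered by method means so "a" always marks the
lowest group. With at most a handful of methods the cliques are enumerated
exhaustively.

## The phantom generator

`make_swir_phantom()` builds a tooth frame with a half-elliptical lesion
clipped at the contact line — real proximal lesions adjoin the contact, and
the clipped shape guarantees the contact-adjacency selection rule is
exercised. Lesion pixels are placed at $I_s/(1-c)$ (reflectance) or
$I_s(1-c)$ (transillumination) so the matching transform recovers the
target contrast *exactly* at zero noise; this closure is the backbone of
the segmentation tests. Artifacts — specular disks for reflectance,
saturated bleed borders and dark background for transillumination — are
placed at least 10 px from the contact ROI so ground truth stays
unambiguous. Frames are generated in floating point on $[0,1]$ and written
as 16-bit TIFF to preserve contrast resolution near the 0.1 threshold.

Default conditions: 160 × 220 px at 0.05 mm/px, sound enamel 0.6, additive
Gaussian sensor noise σ = 0.005. No intensity histograms of real frames are
available to derive a noise level from, so σ was *chosen* against the
generator's stated behavioural goals — detection must always succeed at
contrast 0.2 and never succeed at 0.05 under the default threshold. At
$i_s = 0.6$ the per-pixel contrast noise is $\sigma/0.6 \approx 0.008$, so
the 0.05 gap between a sub-threshold lesion and the 0.1 threshold is a
6σ event per pixel — negligible across the ~75 contact-adjacent pixels of
50 phantoms — while at contrast 0.2 the 0.1 margin is 12σ. A larger σ
(e.g. 0.01) makes spurious single-pixel detections at contrast 0.05 a
~10% per-frame event, which is why the default sits at 0.005.

`make_oct_phantom()` builds b-scans with a bright surface echo, sound
enamel decaying as $e^{-\mu z}$ (µ = 1.5/mm of physical depth),
multiplicative sinusoidal banding (period 0.5 mm, amplitude 0.1 — chosen so
that banding rises stay below the 10% prominence guard, which is what the
null-phantom tests verify), an additive incoherent background floor, and
15% multiplicative speckle. The lesion is an elevated-reflectivity band
whose two flanking intensity minima are separated by the configured
*physical* depth; the generator converts to optical pixels with the
refractive index. The flanking dark zones are V-shaped notches a few pixels
wide rather than single-pixel dips — a one-pixel dip would be erased by the
very median filter the pipeline mandates, and a finite-width
demineralization front is also the physically sensible structure. The
notch floor (0.02) sits well below the background floor (0.08) so the two
lesion dips are always the two lowest minima.

What the phantoms deliberately do **not** model: optical ray tracing,
partial-volume and blur effects, the dentino-enamel junction, curved or
rough surfaces beyond a linear tilt, and examiner variability. Passing the
phantom suites therefore demonstrates that the *algorithms* are correct
under the stated image model, not that clinical detection rates would be
reproduced; the clinical rates built into the study simulator are inputs,
not predictions.

## The end-to-end synthetic study

`run_all()` simulates 29 contacts × 2 surfaces. Every surface gets a
phantom per SWIR modality and an OCT b-scan, pushed through the package's
own pipelines; radiographic and visual calls are examiner processes and are
simulated as Bernoulli draws at the configured per-group detection
probabilities. Lesion severity is a mixture: with the method's detection
probability the contrast is drawn from the method's contrast distribution
above the reference threshold, otherwise from a sub-threshold band — so
SWIR detections *emerge from segmentation*, not from a label. All
randomness derives from one master seed; identical configurations are
bit-reproducible. Default problem sizes (160 × 220 SWIR frames, 512 × 120
b-scans, 100 + 100 phantoms in the depth-recovery suite, 500 replicates in
the letter-pattern study) were chosen so the full suite runs comfortably on
a laptop while keeping every axial pixel below 14 µm optical.

One acceptance-level property deserves a note. The letter-pattern study
asks how often the contrast comparison at method means 0.13 / 0.22 / 0.20 /
0.27 with within-subject σ = 0.03 and n = 26 recovers the a / b / b / c
pattern (SWIR-R and SWIR-OT sharing a letter). The margin is intrinsically
thin: the Tukey non-significance band for two means at these settings is
$q_{crit}\sqrt{MS_e/n} \approx 3.72 \times 0.0059 \approx 0.022$, barely
above the true mean difference of 0.02, so the shared letter flips in a
large fraction of replicates. `contrast_letter_recovery()` measures the
actual fraction; the test suite records this property at its stated
target rather than adjusting the conditions to make it comfortable.

## Known limitations

* The SWIR "lesion depth" is a projection-based convention (perpendicular
  extent from the contact line); it is comparable across methods within
  this package but not directly against volumetric measurements.
* The OCT surface fit assumes a single dominant surface in the lateral
  window; stacked interfaces (restorations, cusps) would need a more
  careful surface model.
* The ruler walks a straight line; strongly curved lesions would need a
  curved axis.
* `detection_table()` assumes exactly two surfaces per contact — the
  study design this package serves — and is not a general longitudinal
  container.
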