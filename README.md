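# swircaries

Detection and measurement of interproximal (Class II) caries lesions in
short-wavelength infrared (SWIR) images and cross-polarization optical
coherence tomography (CP-OCT) b-scans, with the statistics used to compare
imaging methods against radiography.

Dental enamel is nearly transparent between 1000 and 2300 nm, while
demineralized (carious) enamel scatters SWIR light strongly. A proximal
lesion therefore appears *bright* in occlusal reflectance imaging (SWIR-R)
and *dark* under occlusal or proximal transillumination (SWIR-OT, SWIR-PT).
CP-OCT resolves the lesion in depth as a band of elevated subsurface
reflectivity. This package is for imaging researchers who need the full
analysis chain behind such studies:

* **Contrast-map segmentation** of SWIR frames. With `I_t` the target pixel
  and `I_s` the mean sound-enamel intensity next to the contact, the
  contrast is `(I_t − I_s)/I_t` for reflectance and `(I_s − I_t)/I_s` for
  transillumination. Pixels with contrast below 0.1 are removed, and only
  mask components adjoining the proximal contact are kept as the lesion —
  which is what rejects specular highlights and direct-light bleed. Lesion
  area, mean contrast, and penetration depth follow automatically.
* **Radiographic lesion contrast** `(I_s − I_L)/I_s` with the sound region
  directly above/below the lesion, plus mm-scale transfer from a calibrated
  SWIR image via the matched mesial–distal tooth span.
* **CP-OCT lesion depth**: kernel-3 median despeckling, a surface-normal
  cylindrical ruler whose profile is the mean intensity in a 100 µm disk
  around the axis, depth as the axial distance between the two
  lowest-intensity minima, divided by the enamel refractive index (1.6) to
  convert optical to physical distance. A 7 mm air scan range reaches only
  7/1.6 ≈ 4.4 mm into enamel.
* **Study statistics**: per-method detection rates, two-sided Fisher exact
  comparisons against radiography, one-way repeated-measures ANOVA on
  lesion contrast and depth with complete-case removal, Tukey post-hoc
  comparisons, and compact letter displays.
* **Synthetic phantoms** for every modality with exact ground truth, so the
  entire chain is testable without clinical images, and a `run_all()`
  driver that simulates a 29-contact (58-surface) study end to end.

## Worked example

Generate a noise-free reflectance phantom with true lesion contrast 0.2,
segment it, and recover the truth:

```r
library(swircaries)

ph  <- make_swir_phantom(phantom_config(modality = "reflectance",
                                        lesion_contrast_true = 0.2,
                                        noise_sigma = 0))
seg <- segment_lesion(ph$image, ph$roi)
seg
#> <lesion_segment> 552 px (1.38 mm^2), mean contrast 0.200, depth 0.900 mm
tidy(seg)
#> # A tibble: 1 x 6
#>   detected area_px area_mm2 mean_contrast depth_px depth_mm
#>   <lgl>      <int>    <dbl>         <dbl>    <dbl>    <dbl>
#> 1 TRUE         552     1.38         0.200       18      0.9
```

The segmented 552-pixel component is exactly the generated half-elliptical
lesion: its mean contrast equals the configured 0.2 because the generator
places lesion pixels at `I_s/(1 − c)`, the inverse of the reflectance
transform. The depth (0.900 mm) is the component's extent perpendicular to
the contact line times the 0.05 mm/px scale.

Measure lesion depth on a speckled CP-OCT phantom:

```r
op <- make_oct_phantom(phantom_config(modality = "oct_bscan",
                                      oct_lesion_depth_true = 1.069))
oct_lesion_depth(op$bscan)
#> <depth_measurement> lesion depth 1.062 mm (physical)
max_physical_range(op$bscan)
#> [1] 4.4
```

The measured 1.062 mm is the distance between the two lowest intensity
minima along the surface-normal ruler (they bracket the lesion band),
divided by the refractive index 1.6 — within one axial pixel of the 1.069 mm
ground truth despite 15% multiplicative speckle.

Run a full synthetic study and summarise it:

```r
rep <- run_all(study_config(seed = 1))
rep$n_surfaces
#> [1] 58
dplyr::filter(rep$fisher, group == "opposing", method == "swir_r")[, c("rate", "rate_ref", "p_value")]
#> # A tibble: 1 x 3
#>    rate rate_ref   p_value
#>   <dbl>    <dbl>     <dbl>
#> 1  0.93     0.41 0.0000466
glance(rep$anova_contrast)
#> # A tibble: 1 x 7
#>   measure  statistic    df df_error  p_value n_complete n_methods
#>   <chr>        <dbl> <dbl>    <dbl>    <dbl>      <int>     <int>
#> 1 contrast      50.7     3       81 1.51e-18         28         4
```

29 contacts contribute 58 lesion surfaces. The SWIR-R detection rate on the
surfaces opposite the restorations is far above the simulated radiographic
rate (Fisher p ≪ 0.05), and the repeated-measures comparison of lesion
contrast across radiograph/SWIR-R/SWIR-OT/SWIR-PT is strongly significant,
with the compact letter display in `rep$report` grouping the methods.

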