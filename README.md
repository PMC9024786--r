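# retimetrics

Quantitative biomarkers of photoreceptor degeneration from multimodal
retinal imaging, with a fully synthetic validation pathway.

In retinitis pigmentosa (RP), degeneration advances concentrically toward
the fovea.  Three modalities track it at different scales, and clinical
studies of *USH2A*-associated RP relate them to pick trial endpoints:

| Modality | Biomarkers |
|---|---|
| Fundus autofluorescence (FAF) | inner/outer hyperautofluorescent ring diameters (IR, OR) |
| SD-OCT B-scan | ellipsoid zone (EZ) and external limiting membrane (ELM) widths; normalised EZ reflectance from a 1000-µm longitudinal reflectivity profile |
| AOSLO (confocal + split detection) | foveal cone density at 100 µm eccentricity; intact macular photoreceptor mosaic (IMPM) diameter |

The package implements, for each eye: the caliper measurements
(half-height ring borders; presence-run band widths with window-exceeded
flags), the LRP pipeline (display-to-linear transform, six-layer peak
labelling, EZ/inner-retina reflectance ratio), automated cone detection
with modality choice and sliding-window mosaic border finding, and the
cohort statistics: paired-eye averaging, Pearson R²/p, mean-difference
agreement, and a continuous two-segment ("biphasic") linear fit of cone
density on EZ width with the breakpoint found by exhaustive grid search —

y = a + b₁·min(x − c, 0) + b₂·max(x − c, 0),  ĉ = argmin over a 25-µm grid of SSE(c).

Because the underlying patient images are not publicly deposited, the
package also contains a synthetic retina generator (`sample_cohort()`,
`render_faf()`, `render_oct_bscan()`, `render_aoslo()`) that draws per-eye
ground truth with the published cohort dispersion and cross-modality
offsets, renders all three modalities, and lets every measurement be
validated by parameter recovery.  A packaged clinical table
(`inst/extdata/table1.csv`) carries the cohort demographics, *USH2A*
variants, axial lengths and acuities used by the demographic statistics.

## Worked example

```r
library(retimetrics)

tab <- read_subject_table(system.file("extdata", "table1.csv",
                                      package = "retimetrics"))
summary_stats(tab$age)
#> n = 16  mean = 36 +/- 14.17 (sample SD)  range = [19, 55]
pearson_r2(tab$age, combine_paired_eyes(tab$bcva_od, tab$bcva_os))
#> R^2 = 0.149, p = 0.14 (n = 16; y = 0.984 + -0.00596 x)
count_variant_carriers(tab, "c.2299delG")
#> [1] 5
```

Age does not significantly predict acuity in this cohort (R² = 0.149,
p = 0.14), and five of sixteen subjects carry the common c.2299delG
allele.  A synthetic eye measured end to end:

```r
cfg <- render_config()
eye <- sample_cohort(1, seed = 4, config = cfg)$eyes[[1]]
ao  <- render_aoslo(eye, cfg)
m <- analyze_eye(render_faf(eye, cfg), render_oct_bscan(eye, cfg),
                 ao$confocal, ao$split, cfg)
round(m$ez_width_um)            # 2214   (truth 2199)
round(m$cone_density_mm2)       # 49400  (truth-coordinate count 48750)
round(m$impm_diameter_um)       # 2890   (truth 2872)
```

and the full 16-subject recovery study (about 4–5 minutes):

```r
study <- run_synthetic_study(16, seed = 1)
study$report
#> Biomarker report - 16 subjects
#>
#> Cross-modality agreement (per-subject means):
#>   ir_diameter_um   vs ez_width_um        R^2 = 0.998  diff = -30 +/- 47 (n = 16)
#>   or_diameter_um   vs elm_width_um       R^2 = 0.999  diff = -45 +/- 32 (n = 16)
#>   ez_width_um      vs impm_diameter_um   R^2 = 0.996  diff = -314 +/- 73 (n = 16)
#>   ir_diameter_um   vs impm_diameter_um   R^2 = 0.995  diff = -344 +/- 83 (n = 16)
#>
#> Hinge fit, cone density vs EZ width: breakpoint 2731 um
```

The report shows near-unity agreement between IR diameter and EZ width,
recovery of the injected −8/−39/+292 µm modality offsets within two
standard errors, and a biphasic breakpoint within the 25-µm grid
neighbourhood of the injected 2700 µm.

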