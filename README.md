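# octawide

Quantitative microvascular analysis of wide-field optical coherence
tomography angiography (OCTA).

Diabetic retinopathy damages the retinal capillary bed, and much of the
damage in its nonproliferative stages sits in the retinal periphery, outside
the small macular fields most OCTA protocols image. `octawide` implements a
complete quantification pipeline for wide-field (typically 12 × 12 mm,
500 × 500 sample) en-face angiograms, for researchers who want objective,
regional perfusion metrics from such scans — plus the statistical machinery
to compare them across severity groups, and a synthetic phantom generator so
the whole chain is testable against exact ground truth without patient data.

## The pipeline

For an en-face angiogram *I* (intensities in [0, 1], physical extent known):

1. **Large-vessel segmentation.** A combined Gabor and Hessian vesselness
   filter enhances bright tubular structures: the maximum over 12
   orientations and wavelengths {6, 10, 16} px of an even-phase, zero-DC
   Gabor bank, and a Frangi-style Hessian vesselness over scales
   {2, 4, 8} px (bright ridges only, λ₂ < 0), each normalised to [0, 1] and
   combined per pixel by max. The response is binarised (Otsu by default)
   and specks below 0.01 mm² removed, giving the large-vessel mask *V*.
2. **Capillary segmentation.** A sliding window (3 × 3 mm, step 1.5 mm)
   moves over the field; in each window *w* the threshold is
   *t_w* = 0.35 · mean(*I* over *V* ∩ *w*), falling back to the global
   vessel mean in vessel-poor windows. Overlapping windows vote per pixel
   (majority, ties perfused); vessel pixels are then removed so the
   capillary mask *C* is disjoint from *V*.
3. **Nonperfusion and dropout.** Low-OCT-signal areas (from the paired
   structural image) are excluded everywhere. The nonperfusion map is the
   complement of *V* ∪ *C* in the valid area; its 8-connected components
   that survive manual FAZ/optic-disc exclusion and whose area strictly
   exceeds **0.36 mm²** are capillary dropout. Smaller components are
   normal intercapillary space.
4. **Regional metrics.** Over each region *R* (the wide field, the central
   6 × 6 mm square, the remaining square annulus, and 5 × 5 uniform
   2.4 mm blocks):

   - TPD = |(*V* ∪ *C*) ∩ *R*| / |*R*| · 100 (total perfusion density)
   - CPD = |*C* ∩ *R*| / |*R*| · 100 (capillary perfusion density)
   - LVD = |*V* ∩ *R*| / |*R*| · 100 (large vessel density)
   - CDD = |dropout ∩ *R*| / |*R*| · 100 (capillary dropout density)

   Exclusions leave numerator and denominator together, and
   TPD = CPD + LVD holds as an identity.

Cohort statistics mirror the study design such data come from: test-retest
repeatability as the two-way random-effects, absolute-agreement,
single-measure ICC with the 0.50/0.75/0.90 bands; z-normalised group
contrasts by nonparametric bootstrap that resamples *subjects* (carrying
both eyes, respecting intra-subject correlation) with percentile CIs and
Benjamini-Hochberg FDR control; linear orthogonal trend contrasts across
ordered severity groups; and ROC/AUC comparison of correlated curves by the
DeLong method.

## Worked example

```r
library(octawide)

cfg <- phantomConfig(seed = 42, nDropoutPatches = 6L, eccentricityBias = 3)
ph  <- generatePhantom(cfg)          # angiogram + structural + ground truth
ph$angiogram
#> Angiogram 'phantom_seed42' (unknown): 500 x 500 px over 12 x 12 mm
#>   intensity range [0.026, 1.000], pixel 0.024 x 0.024 mm

res <- processEye(ph$angiogram, ph$structural)
m <- res$metrics
m[m$region %in% c("wide", "central6", "annulus"),
  c("region", "TPD_pct", "CPD_pct", "LVD_pct", "CDD_pct")]
#>     region TPD_pct CPD_pct LVD_pct CDD_pct
#> 1     wide   55.26   49.62   5.644   6.421
#> 2 central6   58.14   50.40   7.736   1.426
#> 3  annulus   54.30   49.36   4.947   8.086

head(res$dropoutRegions[, c("label", "area_mm2", "centroid_x_mm",
                            "centroid_y_mm", "touches_border")], 3)
#>   label area_mm2 centroid_x_mm centroid_y_mm touches_border
#> 1     1 1.811520      2.473003     0.9185285           TRUE
#> 2     2 1.494144      1.568466     6.1685089          FALSE
#> 3     3 1.356480      9.056239     9.4399541          FALSE
```

Reading the output: the eye is 55.3% perfused overall, decomposing exactly
into 49.6% capillary and 5.6% large-vessel perfusion; 6.4% of the valid
area lies in intercapillary gaps larger than 0.36 mm². The
eccentricity-biased phantom places its dropout peripherally, so annulus CDD
(8.1%) far exceeds central CDD (1.4%) — the regional signature of early
peripheral nonperfusion. Against the generator's ground truth the designed
wide-field CDD of 6.42% is recovered at 6.42%.

Real scans enter through `readAngiogram()`/`readStructural()` (grayscale
PNG/TIFF plus a JSON sidecar carrying `extent_mm` and identifiers), with
manual FAZ/optic-disc masks as 0/255 PNGs via `readMask()`. A thin
command-line front end with `simulate`, `segment`, `cohort`,
`repeatability` and `heatmap` subcommands is installed at
`system.file("scripts/octawide-cli.R", package = "octawide")`.

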