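# isletquant

Semiautomated quantification of pancreatic endocrine cell masses from
dual-channel immunofluorescence sections, with the companion
normalizations used in islet physiology assays.

## The problem

Beta-cell mass is routinely estimated from pancreas sections dual-stained
for insulin (green) and somatostatin (red): islet perimeters are drawn by
hand, and within each islet the hormone-positive area must be separated
from unstained islet tissue. Doing this with one global intensity cutoff
fails because staining intensity varies between islets and the two
fluorophores bleed into each other's channels. `isletquant` implements
the per-islet approach:

1. **Bleed-through correction** — mutual subtraction of the red and green
   channels, both computed from the originals and clamped at zero, so
   each corrected channel keeps only its own signal.
2. **Per-islet histogram thresholding** — for each hand-drawn islet
   region, the insulin channel is segmented with **Otsu's method**
   (maximizing the between-class variance
   σ²\_B(t) = ω₀ω₁(µ₀ − µ₁)²) and the somatostatin channel with
   **Kapur's maximum-entropy method** (maximizing H₀(t) + H₁(t), the
   summed Shannon entropies of the two intensity classes). Thresholds
   are computed from each islet's own 256-bin min–max histogram;
   hormone-positive pixels are those strictly above the threshold edge.
3. **Morphometry** — areas in µm² (pixel counts × pixel size², default
   0.65 µm/px), equivalent-circle diameter d = 2√(A/π), binary size
   classes at a 100 µm cutoff (strict: d < 100 µm is "small"), and
   per-animal pooled summaries — beta-cell % is
   100 · Σ insulin-positive area / Σ islet area, not a mean of
   per-islet ratios.

Assay-side, the package provides fold-over-basal secretion, the
stimulation index 100·s/(s+c) (secreted as % of total hormone content),
four-parameter logistic EC50 fitting
r(d) = bottom + (top − bottom)/(1 + (EC50/d)^hill) with log-scale EC50
standard errors, ΔCt relative expression 2^(−ΔCt), and fura-2
delta-ratio (F340/F380) quantification.

Because every stage is validated against synthetic data, the package
also ships a seeded generator producing dual-channel islet images (disk
islets, interior insulin cores, peripheral somatostatin blobs,
bleed-through, noise) together with exact ground truth.

## Worked example

```r
library(isletquant)

sim        <- generate_islet_image(islet_image_params(), seed = 1)
regions    <- islet_region_set(sim$mask, labeled = TRUE)
m          <- measure_section(sim$section, regions)
m[, c("islet_id", "area_um2", "insulin_area_um2", "equiv_diameter_um", "size_class")]
#>   islet_id area_um2 insulin_area_um2 equiv_diameter_um size_class
#> 1        1     2821             1832             59.93      small
#> 2        2     3559             2316             67.32      small
#> 3        3     2813             1828             59.85      small
#> 4        4     2554             1659             57.03      small
#> 5        5     5183             3366             81.24      small

summarize_pancreas(m, "synthetic")
#>   animal_id n_islets total_islet_area_um2 mean_islet_area_um2 beta_cell_percent
#> 1 synthetic        5                16930                3386             64.98
#>   delta_cell_percent n_small_islets n_large_islets
#> 1               9.98              5              0

sim$truth$true_beta_percent_pooled
#> [1] 64.97966
```

All five simulated islets are found, each is correctly classed as small
(diameters 57–81 µm < 100 µm), and the pooled beta-cell percentage
(64.98%) reproduces the generator's ground truth — at the default
signal-to-noise the per-islet thresholds sit inside the gap between
background and insulin signal, so segmentation is pixel-exact.

Dose–response, on the fold-over-basal scale:

```r
d <- generate_dose_response(sigma = 0.1, seed = 42)
fit_dose_response(d$dose_uM, d$response, fix_bottom = 1)
#> <dose_response_fit> EC50 = 1203 +/- 311 uM, hill 0.767, [1, 2.85]
```

a single noisy realization of the true curve (EC50 950 µM, hill 1, top
2.7); the estimate is within 1 SE of the truth.

## Analysis workflow

The `analysis/` directory holds thin numbered drivers over the package:

| script | what it does | writes |
|---|---|---|
| `analysis/01_simulate.R` | two-group synthetic cohort (3 animals × 2 sections each) with ground truth | `scratch/simulated/`, `results/cohort_truth.csv` |
| `analysis/02_measure.R` | full morphometry over the cohort, truth comparison | `results/per_islet.csv`, `results/per_animal.csv`, `results/recovery_summary.csv` |
| `analysis/03_assay.R` | secretion folds, stimulation indices, EC50 fit, ΔCt, Ca²⁺ delta ratio | `results/assay_conditions.csv`, `results/assay_summary.csv` |

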