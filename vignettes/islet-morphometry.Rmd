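---
title: "Per-islet segmentation and morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-islet segmentation and morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletquant)
```

This vignette is the package's own account of the methods it implements:
the model behind each step, the tunable parameters and why their
defaults are what they are, what the synthetic generator does and does
not emulate, and the design decisions taken where the procedure was
genuinely open.

## The measurement model

A section is a pair of co-registered intensity images: green = insulin
immunofluorescence (beta cells), red = somatostatin (delta cells), with
an optional nuclear channel that is carried but never analyzed. Islet
perimeters are an *input* — hand-drawn masks aligned pixel-for-pixel
with the section — because outlining islets against exocrine tissue is
the step that resists automation; what the package automates is
everything after it.

**Bleed-through correction.** Fluorophore crosstalk adds a fraction of
each channel's signal to the other. With signals that are spatially
disjoint at the cell scale (insulin cores vs peripheral delta cells),
mutual subtraction removes the leaked component: `red' = max(red −
green, 0)` and `green' = max(green − red, 0)`, **both computed from the
original arrays**. The symmetric form was chosen over sequential
overwriting (correct red, then use corrected red to correct green)
because only the symmetric form treats the two channels identically and
leaves each containing only its own signal; the sequential variant makes
the result depend on an arbitrary channel order. The subtraction is
exact when the two stains do not co-localize in the same pixel; where
they do, both corrected channels lose signal — a known limitation shared
by any subtractive unmixing.

**Per-islet thresholding.** Each islet region gets its own 256-bin
equal-width histogram spanning that region's min–max intensity range.
Using per-region (not global) histograms makes thresholds adaptive to
between-islet staining variability, which is the point of the method.
The insulin channel is split by Otsu's criterion — maximize the
between-class variance $\sigma_B^2(t) = \omega_0\omega_1(\mu_0-\mu_1)^2$
— and the somatostatin channel by Kapur's criterion — maximize
$H_0(t)+H_1(t)$, the summed Shannon entropies of the class-renormalized
histograms, with $0\log 0 = 0$ and natural logarithms (the base only
rescales the objective). Kapur's criterion is sometimes loosely described
as entropy *minimization*; the quantity actually optimized in the
standard formulation, and here, is the maximum of the summed class
entropies.

Numerical conventions, stated because off-by-one choices here change
areas:

* the returned threshold is the **upper edge** of the last background
  bin, and foreground is **strictly greater** than that edge;
* ties across splits are broken toward the **smallest** threshold
  (favoring the more sensitive foreground). Because analytically tied
  splits (e.g. equal-mass classes) can differ in the last bits under
  different summation orders, objectives within `1e-9` relative of the
  maximum are treated as tied;
* a region that is constant in a channel has no threshold: it is
  flagged (`constant_green` / `constant_red`) and contributes zero
  hormone-positive area. No fallback to a global threshold is applied —
  a degenerate region is a data problem the user should see, not paper
  over;
* with min–max binning both thresholds are shift-equivariant: adding a
  constant to all intensities moves the threshold by the same constant
  (a tested invariant).

**Morphometry.** Areas are pixel counts scaled by the squared pixel
size (default 0.65 µm/px). Islet "diameter" is the equivalent-circle
diameter $d = 2\sqrt{A/\pi}$: it is deterministic, orientation-free and
exact for the generator's disk islets; a Feret-style caliper diameter
would differ on elongated islets but is out of scope. Size classes are
binary at a configurable cutoff, default 100 µm, with a **strict**
inequality: $d < 100$ µm is small, $d = 100$ µm is large. Per-animal
summaries pool all sections: beta-cell % is
$100\sum A_{ins} / \sum A_{islet}$ (area-weighted), not the mean of
per-islet ratios — the two differ whenever islet sizes vary, and the
pooled form is the one that corresponds to "insulin-positive area
relative to total islet area". Per-section summaries are also emitted
for analyses that average over sections; both views are provided because
either unit of analysis is defensible. Islets touching the image border
are measured but flagged (`touches_border`), leaving the exclusion
decision to the user. Section spacing (default 250 µm) and series index
are carried as metadata only; no stereological volume extrapolation is
attempted.

**Connected components.** Binary masks are labeled under 8-connectivity
by default — diagonal-touching pixels are one islet, the common
morphometry convention — with 4-connectivity available. Labels are
assigned in raster-scan (row-major) order of each component's first
pixel so outputs are reproducible across runs and platforms. Labeled
input masks are accepted; a labeled "region" that is not a single
connected component, or a component carrying two labels (overlapping
perimeters), is an error rather than a silent merge.

## Assay normalizations

* **Fold over basal**: each sample divided by the mean of the
  non-stimulated group, making the basal mean the unit. Scale-invariant
  by construction.
* **Stimulation index**: $100\,s/(s+c)$ with $s$ secreted and $c$ the
  lysate (residual) content. "Total content" is taken to include the
  secreted fraction, since what was secreted was part of the islets'
  content at the start of the incubation; the alternative convention
  $100\,s/c$ is available via `mode = "lysate"` because reports are not
  always explicit about the denominator. In the default mode the index
  is bounded in [0, 100] and monotone in both arguments.
* **Dose–response**: 4PL
  $r(d) = b + (t-b)/(1+(\mathrm{EC}_{50}/d)^h)$ fitted by
  Levenberg–Marquardt least squares with EC50 parameterized on the log
  scale (the scale on which it is approximately normal). `se_ec50` is
  the delta-method SE; recovery simulations summarize EC50
  geometrically and build CIs on the log scale, the convention of
  dose–response practice. On the fold scale the lower asymptote can be
  pinned at 1 (`fix_bottom = 1`), which stabilizes fits when few doses
  sample the lower plateau. Constant responses return
  `converged = FALSE` rather than an error. An EC50 outside the fitted
  dose range is flagged `extrapolated`.
* **ΔCt**: $Ct_{target} - Ct_{ref}$, relative expression
  $2^{-\Delta Ct}$ (exactly halving per cycle); technical replicates
  are averaged on the Ct scale *before* subtraction.
* **Fura-2 delta ratio**: ratio series $F340/F380$ on
  background-corrected channels ($F380 > 0$ required), delta ratio =
  mean over the response window minus mean over the baseline window. A
  window mean, not a peak, is used — the summary is the sustained
  response level.
* Group comparisons (t tests, ANOVA, multiplicity corrections) are
  deliberately not wrapped: standard `stats`/`multcomp` routines apply
  directly to the tables the package emits.

## The synthetic generator

`generate_islet_image()` renders what the pipeline needs to be tested
against, not photorealism: non-overlapping disk islets (lognormal
diameters, default meanlog $\log 70$ µm, sdlog 0.25 — the small-islet
regime where size classification is interesting), an interior concentric
insulin core covering a set fraction of the islet area (default 0.65, a
typical rodent beta-cell share), peripheral somatostatin blobs confined
to the annulus outside the core (delta cells sit at the islet mantle),
a constant background offset (20), signal levels 180 (insulin) and 150
(somatostatin), additive Gaussian noise (sd 10, i.e. insulin
signal-to-noise ≈ 18 — flat-field scanner images at this magnification
are far from shot-noise-limited, so Gaussian noise with interpretable
variance was preferred over Poisson), and symmetric bleed-through
(default α = 0.1): `observed_red = true_red + α·true_green + background
+ noise`, and symmetrically for green. Intensities are rounded and
clamped to the 16-bit range so written TIFFs round-trip bit-for-bit.
All randomness flows from one seed through one stream; the caller's RNG
state is restored.

Disks were chosen because their areas are analytically known, making
geometry tests exact; real islets are irregular, their hormone
territories interdigitate, illumination is uneven, and perimeters are
drawn with human error. Passing recovery tests on this generator
therefore demonstrates the *algorithmic* correctness of correction,
thresholding and bookkeeping — not robustness to every pathology of
real slides.

At the default settings the corrected-channel class separation
(≈ 160 intensity units) is an order of magnitude wider than the noise,
so per-islet thresholds fall inside the gap and recovery of masks and
beta-cell % is exact; pushing `noise_sd` and `bleedthrough_alpha` up
degrades recovery monotonically (a tested property).

The dose–response generator's default grid is eight two-fold steps from
125 µM to 16 mM. A recovery simulation has to bracket the quantity it
validates: this grid places the true EC50 (950 µM) mid-range and samples
both asymptotes (the top dose reaches ≈ 94% of the plateau). Grids
truncated near the EC50 — e.g. stopping at ~4× EC50 — leave the upper
plateau unidentified and make the EC50 estimate right-skewed as a
property of the *design*; validating the estimator on such a design
would conflate the two. Noise is additive Gaussian (default σ = 0.1 on
the fold scale, 4 replicates per dose), matching the spread of
replicate fold measurements in static secretion assays.

The secretion generator draws lognormal concentrations (CV 0.26 by
default, the relative spread of a basal group at 1.9 ± 0.5 ng/ml) and
derives lysate content jointly from a stated true stimulation index, so
both normalizations have exact known answers at CV 0.

## Problem sizes and numerical choices

The test suite and the bundled analyses run on 512×512 px sections
(≈ 333 µm field) with 5 islets, 20 seeds for noisy recovery, 1,000
random histograms for the oracle-equivalence battery and 200 seeded
fits for EC50 recovery — sizes at which every check completes in
seconds while exercising all code paths; nothing in the method depends
on image scale beyond memory. Thresholding is exact arithmetic on
cumulative sums; the only tolerance in the package is the `1e-9`
relative tie band described above. The 4PL optimizer runs with
`ftol = ptol = 1e-13` so that noise-free data are recovered to near
machine precision.

## Known limitations

* Subtractive bleed-through correction assumes non-co-localized stains;
  double-positive pixels lose signal in both channels.
* Hand-drawn perimeters are trusted: overlapping labeled regions are
  rejected, but a sloppy perimeter silently biases areas.
* The equivalent-circle diameter under-reads elongated islets relative
  to a caliper diameter.
* No illumination-field correction, no morphological post-cleaning of
  masks (none is applied by design — thresholded pixels are reported as
  segmented), no whole-slide formats: sections are exported as TIFF.
* Per-animal summaries weight by area across all pooled sections; if
  section sampling is unbalanced across animals, the per-section tables
  should be used instead.
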