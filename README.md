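# bcuSAXS

Scanning small-angle X-ray scattering (SAXS) analysis of the
bone-cartilage unit: from rastered 2D detector frames to per-point
collagen D-period (a fibril pre-strain proxy), fibril orientation and
degree of alignment, five-zone tissue classification, fibre-diffraction
skew correction, and zonal statistics — plus a physics-based synthetic
scan generator that makes every stage verifiable by closed-loop parameter
recovery.

## Who it is for

Researchers analysing scanning-SAXS microdiffraction maps of collagenous
and partially mineralised tissue (articular cartilage, calcified plate,
bone), and anyone who needs a tested, self-validating reference
implementation of the moment-based meridional peak analysis.

## The method in brief

Each scan point's 2D pattern is reduced to a radial profile I(q)
(azimuthal mean over 0.1-1.2 nm⁻¹) and azimuthal profiles I(χ) on the
3rd-order collagen ring. The D-period comes from a non-parametric
method-of-moments estimate of the background-corrected peak:

- q₀ = Σ q·I_b(q) / Σ I_b(q)  (first moment; background is the straight
  line through I(q) at 0.27 and 0.30 nm⁻¹),
- σ² = Σ q²·I_b/Σ I_b − q₀²,  skew = m₃/σ³,
- D = n·2π/q₀ with n = 3,

computed only where the collagen peak area reaches 0.025 a.u. Orientation
χ₀ and alignment ρ = (max−min)/mean come from a zero-baseline Gaussian
fit of the three-ring-corrected I(χ) over [0, 180°). Points are
classified SZ/TZ/DZ/CP/TB by the scalar rules (total intensity ≥ 2.0 a.u.
→ calcified, split CP/TB by depth; ρ < 2.1 → transitional zone;
near-horizontal χ₀ above the TZ → superficial; near-vertical below →
deep). Because azimuthal integration sweeps across the elongated
layer-line reflections of thin fibrils, the integrated peak is
right-skewed and the moment estimate underestimates D; a layer-line
simulation maps skew → q₀ bias and inverts it (`simulateSkewCurve()`,
`correctDPeriod()`). Zonal statistics mirror the two standard protocols:
paired two-tailed t-tests on per-sample zonal means between adjacent
zones, and per-sample one-way ANOVA with Tukey HSD.

## Worked example

A closed-loop run on the regular-scan emulation (21 × 66 points at 40 µm,
desk-scale 512² detector; about two minutes on one CPU):

```r
library(bcuSAXS)

out <- runPipeline(scanPreset("regular"), seed = 11)
subset(out$summary, parameter == "d_period")[, c("zone", "n", "mean", "sd")]
#>    zone   n     mean           sd
#> 1    SZ  63 65.21096 0.0006119186
#> 6    TZ 147 65.51709 0.0006307748
#> 11   DZ 336 65.98164 0.0719917288
#> 16   CP 105 65.73549 0.1100302844
#> 21   TB 735 65.07638 0.1489350044

mean(as.character(out$results$zone) == truthPoints(out$truth)$zone)
#> [1] 1
```

The injected zonal D-periods are SZ 65.2, TZ 65.5, DZ 66.0, CP 65.8
(plateau) and TB 65.0 nm: every zonal mean is recovered within a few
hundredths of a nanometre (the DZ and CP means sit slightly below their
plateau values because each zone includes the interface dip/rise rows),
and all 1386 points classify into their ground-truth zone. The same
closed loop on the detailed preset resolves the interface feature:

```r
det  <- runPipeline(scanPreset("detailed"), seed = 5)
prof <- lateralLineProfile(det$results, "d_period")
# local minimum near the DZ/CP interface -> 65.408 nm,
# calcified-cartilage plateau -> 65.804 nm: a 0.605 % rise over ~70 um
```

Maps are rendered with `renderParameterMap(out$results, "d_period")` and
`renderZoneMap(out$results)`; `out$results` is a per-point data.frame
ready for CSV export.

## Package layout

- `R/geometry.R`, `R/reduction.R` — detector geometry, masks, q/χ
  mapping, profile extraction
- `R/radial.R`, `R/azimuthal.R` — moment peak statistics and D-period;
  azimuthal Gaussian fit, χ₀ and ρ
- `R/zones.R`, `R/zstats.R` — five-zone classification and zonal
  statistics
- `R/skew.R` — layer-line skew simulation and D-period correction
- `R/synthetic.R`, `R/pipeline.R` — forward model and scan generator;
  presets, end-to-end runs, TIFF-directory scan I/O
- `vignettes/bcu-saxs-methods.Rmd` — the model, its assumptions, and all
  numerical choices
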