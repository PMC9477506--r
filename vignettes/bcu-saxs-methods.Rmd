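---
title: "Mapping collagen fibril pre-strain across the bone-cartilage unit with scanning SAXS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping collagen fibril pre-strain across the bone-cartilage unit with scanning SAXS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcuSAXS)
```

## The scientific problem

The bone-cartilage unit (BCU) of a synovial joint is a layered composite:
articular cartilage (superficial, transitional and deep zones — SZ, TZ,
DZ), the calcified plate (CP), and trabecular bone (TB) underneath.
Throughout, the load-bearing scaffold is collagen fibrils whose axial
electron-density repeat — the D-period, roughly 65-67 nm — shifts with the
tensile pre-strain the fibrils carry at equilibrium. Scanning small-angle
X-ray scattering (SAXS) rasters a micro-beam across a thin tissue section
and records one 2D scattering pattern per point; the meridional
reflections of the D-stacking (orders n = 3 and 5 in the accessible
q-window) let each pattern be reduced to a handful of ultrastructural
parameters:

* **D-period** `D = n * 2 * pi / q0` from the centre `q0` of the 3rd-order
  meridional peak (a pre-strain proxy);
* **total SAXS intensity**, the area under I(q), dominated by diffuse
  mineral scattering and used to tell calcified from uncalcified tissue;
* **collagen peak intensity**, the background-corrected 3rd-order peak
  area, a data-quality and collagen-content measure;
* **fibril orientation** `chi0` and **degree of alignment** `rho` from the
  azimuthal intensity distribution of the collagen ring.

This package implements the full analysis chain — reduction, radial and
azimuthal analysis, five-zone classification, skew correction, zonal
statistics — together with a physics-based synthetic scan generator, so
that every stage can be validated by closed-loop parameter recovery: the
generator injects known values, the pipeline must measure them back. No
public raw beamline data accompany the method, which makes the generator
the package's test bed and reference dataset.

## The moment-based D-period estimator

High-resolution beamline optics reveal that the 3rd-order meridional peak
is right-skewed, so symmetric parametric fits (Gaussian and relatives)
mis-centre it. The pipeline therefore treats the background-corrected
segment `I_b(q)` as a distribution and uses its moments:

* first moment `q0 = sum(q * I_b) / sum(I_b)`;
* `sigma = sqrt(sum(q^2 * I_b)/sum(I_b) - q0^2)`;
* skew, the standardised third central moment (`m3 / sigma^3`; the
  conventional definition, adopted here explicitly);
* peak intensity, the bin-width-weighted area under `I_b`.

The diffuse background under the peak is removed by the straight line
through I(q) at 0.27 and 0.30 nm^-1 (each anchor averaged over +/-2 bins
for noise robustness), and negative post-subtraction intensities are
clipped to zero — moments of a signed density are ill-defined, and at peak
scale the clipping is symmetric in the noise. A point is `valid` only when
the peak area reaches 0.025 a.u.; below that, too few coherently
diffracting fibrils are in the beam for a D-period to mean anything
(surrounding fluid, voids). Points with total SAXS intensity at or above
2.0 a.u. are calcified; uncalcified points with `rho < 2.1` are TZ;
aligned points above the TZ band with `chi0` within 30 degrees of
horizontal are SZ, below it within 30 degrees of vertical are DZ. The
30-degree windows quantify the published "around 0/180" and "around 90"
wording (no tolerance is published); they are configurable in
`zoneThresholds()`. Uncalcified aligned points satisfying neither angular
rule fall back to a depth rule and carry a `fallback_depth` trace — the
published protocol does not say what happens to such points, so the
fallback is explicit and auditable rather than silent.

## The azimuthal analysis

I(chi) on the collagen ring is corrected by the three-ring rule
`I_corr = I_peak - (I_inner + I_outer)/2` with the flanking rings 0.03
nm^-1 wide on either side of the 0.27-0.30 nm^-1 peak window (the flanking
widths are a design choice; only the subtraction rule is published). The
corrected profile is fitted with a zero-baseline Gaussian; because a peak
can sit at the 0/180 wrap, the grid is circularly shifted to centre the
empirical maximum before fitting and `chi0` is shifted back modulo 180.
`rho = (max - min)/mean` is evaluated **on the fitted curve** over
[0, 180) — the published wording reads that way; a data-based variant is
exposed via `rhoParameter(dataBased = TRUE)`. For a contained zero-baseline
Gaussian of SD `s` degrees this gives the closed form
`rho = 180/(s * sqrt(2*pi))`, e.g. 3.59 at `s = 20`, which the tests use
as an oracle. Exactly flat profiles short-circuit to `rho = 0`.

Convention, fixed package-wide: depth `y` is micrometres below the
articular surface, increasing downward; `chi0` is the fibril-axis angle
from the horizontal (joint-surface) axis, modulo 180; on the detector the
meridional arcs of a fibril at `chi0` appear at azimuth `chi0 + 90`, and
the azimuthal module removes that 90-degree offset when reporting.

## The synthetic generator

`bcuZonalConfig()` + `buildGroundTruth()` define a virtual bovine BCU core
as depth profiles (the cylindrical core makes the structure effectively
1D), and `renderFrame()` renders each point's detector image from a
fibre-diffraction forward model that factorises in polar detector
coordinates:

```
I(q, chi) = R(q) * W(chi) + B(q)
```

* `R(q)` is the constant-|q| azimuthal average of the layer-line
  reflections. Each meridional order n is an "ellipsoidal" separable
  bivariate Gaussian at `q_axial = n * 2*pi/D` with axial SD `w_a` and
  equatorial SD `w_p`; `w_p` scales as the inverse fibril radius. Because
  azimuthal integration commutes with rotations, `R(q)` is exact for any
  orientation distribution, and for `w_p > w_a` it carries the rightward
  skew that biases the moment estimator — the effect the skew module
  quantifies. For circular reflections the average has the closed form
  `I0(q*qn/w^2) * exp(-(q-qn)^2/(2w^2))` (evaluated through an asymptotic
  expansion of the scaled Bessel function; R's `besselI` costs O(z) at the
  z ~ 1e4 arguments arising here); elongated reflections are integrated
  numerically.
* `W(chi)` is a wrapped Gaussian with 180-degree periodicity centred at
  `chi0 + 90`, concentration `kappa` mapped to angular SD
  `1/sqrt(kappa)` radians with the intrinsic arc footprint `w_p/q_n`
  added in quadrature, normalised to unit circular mean so the angular
  structure never perturbs I(q). `kappa = 0` is exactly isotropic.
* `B(q)` is isotropic diffuse scattering: exponential terms scaled by
  mineral fraction (strong) and collagen density (weak) plus a flat
  instrument floor. The two amplitudes are calibrated analytically, once,
  so a default articular-cartilage point integrates to ~1 a.u. and a
  calcified-plate point to ~5 a.u. over 0.1-1.2 nm^-1 — this pins the
  arbitrary-unit scale so the published thresholds (2.0, 0.025, 2.1) are
  meaningful on synthetic data.
* Counting noise is Poisson per pixel: expected counts are
  `intensity * countsScale` (default 100 photons per a.u.) and the stored
  frame is counts/countsScale; `countsScale = Inf` renders the noise-free
  expectation. Per-point noise seeds derive deterministically from the
  master seed, so identical (config, seed) runs are bit-identical.

The default depth profile injects the canonical zonal values — D-periods
SZ 65.2 / TZ 65.5 / DZ 66.0 / CP 65.8 / TB 65.0 nm; the Benninghof arcade
(horizontal SZ fibrils, kappa 30; unaligned TZ, kappa 0.2; vertical DZ and
CP, kappa 25 and 20; weakly aligned TB, kappa 0.5); mineral fractions 1.0
(CP) and 0.7 (TB); zone boundaries at depths 120, 400, 1040 and 1240 um.
All parameters blend linearly over +/-20 um at boundaries, except the
D-period at the DZ/CP interface, which follows a single piecewise-linear
feature: a drop from 66.0 over the last 40 um of the DZ to a local minimum
of 65.4 nm at the boundary, a rise to the 65.8 plateau over 70 um, the
plateau through the plate, then a 170 um decline to 65.0 below the CP/TB
boundary. A naive cross-blend of per-zone constants would average the dip
away (the blended minimum would sit near 65.5) and the interface gradient
could not be recovered even noise-free, so the knot profile is the
generator's definition of that feature. The TZ/TB kappa ordering
(TZ 0.2 < TB 0.5) reflects that trabecular bone retains weak local
lamellar alignment while the TZ is the isotropic extreme of the arcade;
it also keeps the measured rho ranking faithful to the injected kappa
ranking, since the mineral-rich TB has the higher rho noise floor.

For multi-sample simulations, `sampleEffects = TRUE` adds per-zone
Gaussian offsets to the zonal D-periods with between-sample SDs of 0.3
(SZ, TZ), 0.35 (DZ, CP) and 0.15 nm (TB) — cartilaginous D tracks
per-animal hydration and pre-strain state, while the mineralised-collagen
D of trabecular bone is tightly conserved. At n = 6 these SDs make the
paired adjacent-zone t-tests reproduce the published significance
pattern with high probability (a priori power: DZ-CP non-significant
~0.87, CP-TB significant ~0.98) while single-sample runs (the default,
`sampleEffects = FALSE`) inject the printed values exactly.

**What the generator does not emulate.** Real diffuse scattering from
oriented mineral platelets (the generator's mineral term is isotropic);
detector point-spread, flat-field and polarisation effects; fly-scan
motion blur; the porous cellular texture of trabecular bone (the
generator's TB is laterally homogeneous, so recovered TB maps lack the
patchiness of real scans); intrafibrillar disorder beyond the two width
parameters. Passing recovery tests therefore demonstrates that the
analysis inverts the stated forward model at realistic counting noise —
not that it is robust to every instrumental artefact of a real beamline.

## Desk-scale geometry and problem sizes

The reference geometry is the beamline configuration (Pilatus 2M,
1475 x 1679 pixels of 172 um, 5.8 m, 14 keV), available as
`beamlineGeometry()`. The synthetic presets run on `reducedGeometry()`:
512 x 512 pixels of 300 um at the same distance and energy. Two
properties matter and both are preserved: full azimuthal coverage of the
collagen ring (q3 at ~78 px) with complete annuli to ~0.93 nm^-1, and a
radial q-step (~0.0037 nm^-1) comparable to the rendered peak width
`w_a = 0.0035 nm^-1`. The second is not cosmetic: on a coarser detector
whose pixel q-step exceeds `w_a`, thin q-bins are populated only at
particular azimuths, the orientation weighting couples into the radial
moments, and the D-period acquires an orientation- and mask-dependent
bias of several hundredths of a nanometre. The real detector resolves the
peak (q-step ~ 0.6 sigma) and the desk-scale stand-in must too. Three
further choices address the same pixel-scale sampling problem: the
renderer integrates the collagen term over each pixel's area (2x2
Gauss-Legendre nodes) rather than point-sampling its centre, as physical
pixels do; radial bins are labelled with the mean pixel q of the bin
rather than the bin centre; and the azimuthal ring profiles use a
radially stratified average (mean over radial sub-bins of sub-bin pixel
means), which removes the occupancy weighting that thin cells would
otherwise impose on the sharply peaked ring kernel. What remains on the
peak ring is a few-percent deterministic quantisation texture; the flank
rings and all I(q)-derived quantities are essentially exact (off-peak
bins match the analytic model to ~1e-6, and pixel-area integration
preserves peak area and centroid, hence the D-period). `w_a = 0.0035 nm^-1` itself keeps all zonal
3rd-order peaks at least ~3 sigma inside the 0.27-0.30 nm^-1 background
bracket, so truncation bias stays below ~0.02 nm.

Preset scan sizes are the package's own desk-scale choices: the regular
scan keeps the published 21 x 66 grid at 40 um; the detailed scan covers
a 45 um x 600 um strip at 5 um (9 x 121 points, depths 900-1500 um)
rather than the full 0.4 x 0.4 mm field, which is ample to resolve the
interface dip, rise and plateau that the recovery experiments measure;
the full-length preset is 19 x 250 at 20 um. A full regular-scan
closed loop runs in about two minutes on one CPU.

## Skew correction

`simulateSkewCurve()` renders the 2D reflection for a grid of `w_p/w_a`
ratios in [1, 10], integrates at constant |q|, and applies the
pipeline's own background subtraction and moment estimator, recording
skew, apparent q0 and apparent D. Two windows are exposed: `"pipeline"`
(default) reproduces the measurement estimator exactly — including the
small negative baseline skew its asymmetric bracket imparts — and is what
`correctDPeriod()` inverts; `"peak"` integrates the bare peak over a wide
symmetric window and shows the intrinsic effect (skew exactly zero at
ratio 1, monotone in the ratio, apparent D always below true D for
elongated reflections). The inversion interpolates the monotone upper
envelope of the skew column (the baseline dip at small ratios corresponds
to negligible shifts), refuses extrapolation beyond the simulated range,
and never lowers the apparent D. `zoneSkewCorrection()` applies the
correction per zone, using each zone's median measured `sigma` as the
axial-width proxy and its median skew as the matching point — the
representative-sample usage; per-point correction would require an
independent `w_p` measurement, which the pipeline deliberately does not
attempt.

## Statistics

`zonalMeans()` summarises each parameter per zone over valid points, with
`chi0` averaged by axial circular statistics (modulo 180; a naive mean of
SZ values straddling 0/180 would land near 90). Zones absent from a
sample are missing rows, never zeros, and a sample genuinely lacking a
zone — thin superficial zones are commonly unresolvable — is simply
reported without it. `pairedAdjacentZoneTests()` runs two-tailed paired
t-tests on per-sample zonal means for SZ-TZ, TZ-DZ, DZ-CP and CP-TB,
using only samples with both zones present and flagging pairs with fewer
than three complete pairs as underpowered. `intraSampleAnova()` is the
per-sample protocol: one-way ANOVA with zone as the factor, Tukey HSD
pairwise comparisons, and the conventional star coding. No
multiple-testing correction is applied across the four pairs or across
parameters, matching the published protocol; unweighted means of points
enter the paired tests (point-count weighting is an undocumented
alternative). `lateralLineProfile()` gives the row-wise mean and SEM
depth profile used for the interface-gradient readout.

## Numerical choices and degenerate inputs

* Reduction bins are means, not sums, so profiles do not depend on pixel
  counts per ring; empty bins are `NA`, never interpolated.
* 600 radial bins over 0.1-1.2 nm^-1 and 90 azimuthal bins over
  [0, 180) resolve the peak and arc widths at both geometries.
* The azimuthal fit takes its start values from the profile's argmax and
  circular moments, bounds `s` in [1, 1000] degrees, and declares
  `fit_ok = FALSE` on non-convergence, non-positive amplitude or a
  relative residual norm above 0.5. Dead chi bins are excluded from the
  fit, not interpolated.
* Exactly flat corrected profiles return amplitude 0 and `rho = 0`
  without fitting; `rho` is undefined (NA) when the fit fails or the
  fitted mean is non-positive, and such points rely on the depth
  fallback during classification.
* Per-point analysis failures are isolated: the point is flagged invalid
  and the scan continues (an all-fluid column classifies as INVALID
  without aborting).
* The CP/TB boundary depth is config-supplied (ground truth for
  synthetic scans, a visually clear demarcation in practice); an
  automatic mode takes the deepest row of the topmost contiguous
  high-intensity band.

## Limitations

The forward model's angular factor is exact only in the limit of small
intrinsic arc width (the `w_p/q_n` footprint is folded into the wrapped
Gaussian rather than convolved exactly); its I(q), which drives all
D-period results, is exact. The layer-line profile form (separable
bivariate Gaussian) is an assumption — the published sketch names
"ellipsoidal" reflections without a functional form — chosen as the
simplest shape reproducing the described widths and skew phenomenology.
Zone classification inherits the published scalar rules; it knows nothing
of the calcified-cartilage/subchondral-bone substructure of the plate,
and misclassification on synthetic data is confined to
boundary-smoothing rows. 2D scanning of an intrinsically 3D tissue is
mitigated, not removed, by the cylindrical-core assumption of 1D depth
variation.
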