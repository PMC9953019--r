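---
title: "Methods: pulsatile hemodynamics post-processing and robust factorial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pulsatile hemodynamics post-processing and robust factorial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsewss)
```

# Scope and data model

`pulsewss` implements everything that happens *after* a pulsatile CFD
solver has produced wall shear stress (WSS) and velocity fields for an
abdominal aortic aneurysm study, together with the statistics used to
compare modelling choices across a factorial simulation campaign. The
solver itself (segmentation, meshing, Navier–Stokes integration) is out
of scope; it is replaced by (a) packaged campaign result tables
(`load_reference_table()`, cases 2B–63A, five rheology models, three
inlet profiles) and (b) synthetic generators with analytic ground truth
(`make_waveform()`, `make_wss_field()`, `make_plane_field()`,
`make_factorial_table()`).

All long-format data flow through plain `data.frame`s with columns
`case, rheology, inlet, variable, value`; reference values are stored
at their printed precision so they round-trip exactly as decimal
strings.

# The cardiac waveform and its surrogate

A `waveform` is one period of the cross-sectionally averaged inlet
velocity, sampled uniformly on `[0, T)`. The study conditions the
package emulates are a 1 s cardiac cycle discretized in 200 steps
(0.005 s), a time-averaged speed of 0.0647 m/s and a peak-to-mean ratio
of 4.483. The speed follows from the campaign's mean Reynolds number
(`Re = 2ρŪR/μ`, diameter-based) at the reference radius with
ρ = 1050 kg/m³ and μ = 0.00345 Pa·s; the ratio is the peak-to-mean
Reynolds ratio of the same case. The density is a documented inference:
it is the value under which `α = R√(ωρ/μ)` reproduces every tabulated
Womersley number to two decimals (the also-common 1060 kg/m³ does not).

Because the true waveform shape is not tabulated, `make_waveform()`
uses a deterministic surrogate: a raised trigonometric pulse
`1 + A·g(t)` where `g` is a normalized, zero-mean `cos^{2m}` pulse with
`m = 10` harmonics. Two properties make it a good test substrate:

- every harmonic is below the sample count, so the *discrete* time
  average is exactly the continuous one — the mean is hit to machine
  precision at any grid size;
- the peak time is snapped to the grid, so the max/mean ratio is exact.

The surrogate is band-limited by construction, which is what the
Womersley pipeline assumes of its input; a measured waveform with
content above mode 14 would violate the 0.5% reconstruction contract
and is reported as such by `fourier_decompose()`.

# Womersley profile construction

`womersley_profile()` assembles the analytic oscillatory pipe-flow
solution mode by mode. Three choices deserve comment:

1. **Amplitude calibration.** The textbook solution is parameterized by
   the axial pressure-gradient amplitude per mode, which a waveform
   does not provide. We instead divide each mode shape by its own disc
   average, so that the disc-averaged profile reproduces each waveform
   Fourier coefficient identically. This is the only closed constraint
   consistent with the requirement that Parabolic, Plug and Womersley
   profiles share the same instantaneous mean — the property that makes
   the three inlet conditions comparable in a factorial design.
2. **Mode 0.** The printed oscillatory solution is singular at `n = 0`;
   the steady component is carried by a Poiseuille profile with the
   waveform mean, which is the zero-frequency limit.
3. **Viscosity.** α is always computed with the Newtonian reference
   μ = 0.00345 Pa·s regardless of the bulk rheology, matching how the
   campaign tabulated it.

Complex Bessel functions `J₀`, `J₁` are evaluated by their power
series. At the largest argument the pipeline produces
(|z| ≈ α√14 ≈ 60) the alternating series loses ~6 significant digits to
cancellation, leaving ~10 — two orders more than the 0.5% contracts
require. Disc averages are integrated in the area variable
`v = (r/R)²` (trapezoid), exact for plug/parabolic profiles and
second-order for Womersley shapes; 201 radial points keep the
quadrature error of high-α profiles below 0.01% of the peak.

Degenerate and edge cases: `α → 0` recovers the quasi-steady parabola
(verified at α = 0.1 against `parabolic_profile()` within 1%); no-slip
at `r = R` is exact because the numerator bracket vanishes identically.

# Rheology

The five constitutive laws carry their conventional parameter sets (see
`?rheology_spec`). Numerical choices:

- **Carreau–Yasuda exponent.** The bracket exponent is `(n − 1)/a`, the
  standard shear-thinning form under which μ falls monotonically from
  μ₀ to μ∞. With the packaged parameters all five laws are verified
  non-increasing on a log grid spanning 10⁻³–10⁵ s⁻¹.
- **Regularization.** Casson, Herschel–Bulkley and power-law
  viscosities diverge as `γ̇ → 0`; `apparent_viscosity()` caps them at
  `mu_max` (default 10 Pa·s), the solver-style treatment that keeps
  downstream index computations finite. The cap is configurable because
  it is a numerical device, not physics.
- The frequent claim that all models "converge to Newtonian above
  100 s⁻¹" is treated as qualitative: with these parameters Cs/CY are
  still ≈25% above μ∞ at 100 s⁻¹ and P/HB fall *below* μ∞ at high
  shear. The tests assert the correct asymptotics instead.

# WSS indices

Time integrals use the periodic rectangle rule (mean over samples × T),
which on a uniform grid over `[0, T)` coincides with the periodically
wrapped trapezoid rule and is spectrally accurate for band-limited
series; refining 200 → 400 samples moves synthetic indices by < 0.1%.

`OSI` is undefined (returned `NA`, not 0.5) when the magnitude integral
vanishes: a zero field has no oscillation direction to speak of. `RRT`
uses proportionality constant 1, the convention under which the
packaged campaign's RRT values equal `1/[(1 − 2·OSI)·TAWSS]` in
magnitude; `OSI = 0.5` maps to infinite residence time and is carried
as `Inf`, counted as thrombus-prone by the `RRT > 10 Pa⁻¹` threshold
and excluded from area-weighted averages.

Averages are area-weighted by default. Whether the campaign's published
summaries were area-weighted or element-wise is not stated anywhere;
both modes are provided (`summarize_indices(weighted = FALSE)`), and
only properties that hold under either reading are asserted against the
reference tables.

Thrombus-prone thresholds are strict inequalities (`TAWSS < 0.4 Pa`,
`OSI > 0.3`, `RRT > 10 Pa⁻¹`); boundary values are not prone.

# Plane flow metrics

The "top 15% of peak systolic velocity" band is read as *magnitude*
thresholding — cells with speed ≥ 85% of the plane maximum — rather
than the top 15% of cells ranked by speed. The magnitude reading makes
dispersion a breadth measure with a meaningful ceiling (uniform flow
⇒ 100%); the quantile reading fixes dispersion at 15 by construction
and is retained behind `mode = "quantile"` for sensitivity analysis.
Likewise the band centroid is area-weighted by default with a
velocity-weighted option. Both defaults are documented choices where
the underlying definitions are loose.

Ground-truth values attached by `make_plane_field()` are continuum
limits; tessellated estimates converge to them, and doubling the
resolution of a smooth jet moves both metrics by < 1%.

# Grid convergence

`gci_study()` uses fine-grid-referenced relative errors
`e₁₂ = 100|f₁−f₂|/f₁`, `e₂₃ = 100|f₂−f₃|/f₂` and
`GCI = F_s·e/(r^p − 1)` with `F_s = 1.25`. Under this convention the
asymptotic diagnostic `GCI₂₃/(r^p·GCI₁₂)` reduces *algebraically* to
`f₁/f₂` whenever `p` is the observed order — so it approaches 1 exactly
as the discretization error vanishes, which is the content of the
asymptotic-range condition. This normalization reproduces all three
ratio diagnostics of the packaged reference mesh study to four
decimals. Manufactured sequences `f* + C·hᵖ` recover `p ∈ {0.5, 1, 2,
3}` to 1e-12.

The packaged study's printed order/GCI columns for TAWSS and OSI cannot
be recovered from the tabulated four-decimal solution values (they were
evidently computed at full precision); only the RRT row, where the
grid-to-grid differences are well resolved at the printed precision, is
asserted (order within 0.005). Oscillatory triplets (sign change
between successive differences) are rejected rather than silently
producing a complex logarithm.

# Robust factorial statistics

The campaign is a balanced 5 × 3 design with n = 7 responses per cell.
Exploratory analysis of such data shows strong heteroscedasticity and
occasional extreme cells, so the package implements the trimmed-mean
methodology of Wilcox-type robust ANOVA rather than classical
F-tests:

- **Location/scale.** 20% trimmed means with winsorized variances; the
  squared standard error of a trimmed mean is
  `(n−1)s²_w / (h(h−1))`, `h = n − 2⌊0.2n⌋`.
- **Tests.** Johansen-type Wald statistics on the cell trimmed means
  for both main effects and the interaction, with the small-sample
  adjusted chi-square critical value. p-values are found by scanning
  the significance grid `0.001 … 0.999`: the reported p is the smallest
  level whose adjusted critical value the statistic exceeds. p-values
  therefore have granularity 0.001 and live in `[0.001, 0.999]` — an
  entirely null effect reports 0.999, not 1.
- **Post hoc.** Yuen-type heteroscedastic comparisons of *pooled*
  factor-level trimmed means (n = 35 per inlet level, n = 21 per
  rheology level), with Welch–Satterthwaite degrees of freedom. The
  pooled convention is the default because it reproduces the campaign's
  published contrast estimates to three decimals; averaging per-cell
  trimmed means (available as `pooling = "cellwise"`) differs by a few
  hundredths. Pair ordering is locale-independent case-insensitive
  alphabetical, first minus second.
- **Multiplicity.** Hochberg's step-up adjustment per (response,
  factor) family. Confidence intervals are widened using the
  per-comparison level implied by the step-up sequence (α/k for the
  k-th largest raw p); this is a best-effort construction — the exact
  critical-value recipe behind published robust post hoc CIs is not
  uniquely determined, so adjusted p-values and point estimates, not CI
  endpoints, are the reproduction surface.
- **Evidence labels.** p < 0.005 strong, 0.005 ≤ p ≤ 0.05 weak,
  otherwise none.

The trim proportion 0.2 is the methodology's conventional default and
is confirmed by reproduction: pooled 20% trimmed means recover the
published contrast estimates exactly at their printed precision (e.g.
the OSI_pct Parabolic−Plug contrast of 10.109). With `trim = 0` the
whole machinery reduces to a Welch/Johansen heteroscedastic ANOVA on
ordinary means, cross-checked in the tests against an independent
mean-based implementation, and `yuen_test(trim = 0)` reproduces
`t.test()` exactly.

One structural simplification is inherited deliberately: the same seven
geometries appear in every cell, a repeated-measures structure that the
between-subjects analysis ignores. The package follows that convention
to remain comparable with the published analysis.

## Calibration

`make_factorial_table()` emulates the campaign design: 5 × 3 cells,
n = 7 per cell, Gaussian cell noise with optional per-cell scales
(heteroscedasticity) and multiplicative outlier contamination. Under
the global null (zero effects, homoscedastic noise), 500 simulated
campaigns give type-I error rates near the nominal 0.05 for both main
effects and the interaction; the test band is the 99.7% binomial range
(three standard errors, ±0.029 at 500 replicates) applied to three
rates simultaneously. The interaction statistic runs mildly liberal at
h = 5 retained observations per cell — a known small-sample property of
the adjusted critical value. Contamination checks verify the defining
robustness property: planting one 100× outlier per cell perturbs every
trimmed contrast strictly less than the corresponding untrimmed one.

## What the synthetic generators do not emulate

Synthetic tables draw independent Gaussian (possibly inflated) errors;
real campaign responses are bounded percentages with correlated cells
(same geometries) and skewed tails. Synthetic WSS fields are
single-harmonic with analytically placed directions; solver fields have
broadband content and spatially correlated direction changes. Passing
tests therefore demonstrate correctness of the implemented estimators
and their small-sample calibration under clean conditions — not that
the robust procedure has any particular power profile on real AAA
data. The reproduction of the packaged campaign statistics is the
bridge to real data.

# Problem sizes and runtime

Defaults were chosen so that the full test suite exercises every claim
at meaningful resolution while remaining quick: 200-sample waveforms,
201-point radial grids, 2000-sample time grids for analytic index
oracles, ≥ 1000 random elements for the OSI-bound property, 500
replicates for null calibration. All are arguments, not constants.

# Known limitations

- Inlet profiles are circular-section only; mapping onto non-circular
  patient inlets is upstream of this package.
- No WSS computation from velocity fields, and no transverse/axial WSS
  decomposition beyond the three indices.
- CI endpoints of post hoc contrasts are best-effort (see above).
- The alpha-grid p-value search bounds reported p-values at 0.001;
  smaller values are reported as 0.001, which is immaterial for
  evidence labelling but matters if exact tiny p-values are needed —
  `yuen_test()` returns continuous p-values for that purpose.
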