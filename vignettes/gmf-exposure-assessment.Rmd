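---
title: "Weighted-peak assessment of MRI gradient-field exposure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted-peak assessment of MRI gradient-field exposure: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmfassess)
```

## The assessment problem

MRI gradient coils produce time-varying stray magnetic fields (kHz-band,
complex waveforms) inside the magnet room. Personnel assisting a patient
during acquisition, and accompanying persons, stand in this field. European
regulation limits exposure with frequency-dependent magnetic-flux-density
curves: the *reference levels* (RLs) of Recommendation 1999/519/EC for the
general public and the *low/high action levels* (ALs) of Directive
2013/35/EU for workers (low ALs relate to sensory-effect limits, high ALs to
health-effect limits). Because the gradient waveform is broadband, a
single-frequency comparison is meaningless; the accepted metric is the
**weighted-peak index**, which weights every spectral component by the
inverse limit at its frequency, recombines the components with their
phases, and reports the largest instantaneous magnitude of the weighted
waveform as a percentage. An index of at most 100% means compliant.

This package implements the full assessment chain: the limit curves, the
weighted-peak index for sampled or spectral-line inputs, the decay of the
index with distance from the gantry mouth, the resulting *clearance*
distance (where the index crosses 100%), and EN 50499 Annex E zoning
(Zone 0 / 1a / 1b / 2).

## Limit curves

The four magnetic-flux-density curves (`RL_B`, `LOW_AL_B`, `HIGH_AL_B`,
`LIMB_AL_B`) are stored row-for-row as printed in the regulatory tables in a
versioned YAML file (`system.file("extdata", "limit_tables.yaml", package =
"gmfassess")`), so the numbers are auditable without reading code. Each row
keeps the unit in which the frequency enters the printed formula (Hz, kHz or
MHz) rather than converting coefficients, and segments are lower-inclusive /
upper-exclusive, following the printed "25 ≤ f < 300 Hz" style. All values
are RMS microtesla.

```{r}
limit_curve("LOW_AL_B")
```

Two facts about these curves matter downstream:

* The low-AL and high-AL curves coincide from 300 Hz. Gradient waveforms
  concentrate their energy above that frequency, so the two occupational
  indices of a gradient sequence nearly coincide — a property the tests
  assert on synthetic trains.
* The action-level curves are analytically continuous at every interior
  breakpoint. The printed reference-level table is *not*: at 150 kHz the
  rows 6.25 µT and 0.92/f µT (f in MHz) meet with a 1.9% jump, and at 2 GHz
  0.0046·√f meets 0.20 µT with a 2.9% jump. `curve_continuity()` reports
  these kinks; they are features of the printed table, far above the
  gradient-field band, and are deliberately not smoothed away.

## The weighted-peak index

For a spectral representation \(B(t) = \sum_i A_i \cos(2\pi f_i t +
\varphi_i)\) the index against curve \(L\) is

\[ \mathrm{WP} = 100 \cdot \max_t \Big| \sum_i A_i\, |W(f_i)| \cos\big(2\pi
f_i t + \varphi_i + \arg W(f_i)\big) \Big|, \qquad |W(f)| =
\frac{1}{\sqrt{2}\, L(f)} . \]

The \(\sqrt2\) appears exactly once, in the weight: the tables are RMS while
samples are instantaneous. `rms_to_peak = FALSE` disables it for instruments
that pre-scale.

**Phase models.** `zero_phase` (default) sets \(\arg W = 0\): fully
reproducible and independent of any filter realisation.
`first_order_cascade` adds the phase of a realisable weighting filter,
\(\arg W(f) = \sum_k s_k \arctan(f/f_{c,k})\), with one first-order corner
per slope change \(s_k\) of \(\log 1/L\) versus \(\log f\). The corner set
is the interior breakpoints of the curve *plus* the lower domain edge
(1 Hz for the AL curves), where the realisable filter flattens; with the
edge corner the slope changes of every packaged curve sum to zero, so the
phase returns to zero above the last corner. In both models the *magnitude*
is kept exact (\(1/(\sqrt2 L)\)): this is the convention of established
time-domain weighted-peak implementations, it keeps the single-tone index
exactly equal to the closed form \(100 A/(\sqrt2 L(f))\) at every frequency,
and it makes the two phase models agree for single tones. A fully
cascade-shaped magnitude — the rounded corners of an actual hardware filter
such as a field tester — is available as `magnitude = "cascade"`, non-default,
and differs from the exact magnitude by up to 3 dB per unit slope change at
a corner.

**Back ends.** `wp_index_time()` weights the FFT bins of each channel and
inverse-transforms (bins outside the curve domain are zeroed; a configured
low-cut applies a first-order high-pass, magnitude-only under `zero_phase`).
`wp_index_spectral()` reconstructs the weighted waveform on a time grid of
at least ten periods of the lowest line frequency, doubling the grid until
the maximum changes by less than 0.1% relative. Both back ends agree to
better than 0.5% on band-limited periodic records, and axes of a triaxial
record are combined by instantaneous root-sum-of-squares (the behaviour of
triaxial probes); a per-axis-maximum alternative is exposed but not the
default.

**Windowing.** Records are assessed without amplitude windowing: a window
would distort a peak metric. The synthetic generator always emits an integer
number of periods, so leakage does not arise in tests; for real recordings
the user should supply whole periods where possible.

**Low cut.** Field instruments commonly apply a 30 Hz low-cut to suppress
hum and movement artefacts in the static field; `weighting_spec(low_cut =
30)` reproduces this as a first-order high-pass. DC content is outside the
AL domain (which starts at 1 Hz) and is zeroed there; for the RL curve DC is
weighted by the constant 4 × 10⁴ µT band unless a low-cut removes it.

## Synthetic gradient signals

`gen_waveform()` emulates the waveform *class* of gradient sequences, not
any manufacturer's pulse program (no public gradient amplitude/slew data
exist for the packaged survey): `tone`, `trapezoid_train` (one trapezoidal
lobe per period — rise, plateau, fall, rest; the classic gradient lobe) and
`bipolar_epi_train` (alternating-polarity lobes each half-period, as in EPI
readouts). Defaults follow what is typical for clinical gradient systems:
fundamentals of hundreds of Hz, rise times of order 0.1 ms, so that spectral
energy concentrates above 300 Hz. The unipolar train carries a DC component
by construction; spectral-energy statements therefore refer to the AC
spectrum (DC is outside the AL band and zero-weighted in assessment).

`gen_distance_profile()` generates index-versus-distance samples from the
ground truth \(I(d) = A\,(d+d_0)^{-n}\,(1+\varepsilon)\), with
multiplicative Gaussian noise \(\varepsilon \sim N(0, \sigma)\) emulating
probe-positioning reproducibility (the dominant error source reported for
such measurements; \(\sigma = 0.05\) is used in the recovery tests). All
generators are seed-reproducible and restore the session RNG state.

What the generators do **not** emulate: true multi-axis field orientation
around a magnet (axis gains are a fixed projection), sequence-to-sequence
amplitude variability, near-field multipole structure beyond the single
offset power law, and instrument noise floors. Passing tests on synthetic
data therefore validate the computational chain, not the field fidelity of
any specific scanner.

## Distance decay and clearance

Measured profiles along a departure line from the gantry mouth are fitted
with the three-parameter offset power law

\[ I(d) = A\,(d + d_0)^{-n}, \]

by *unweighted least squares in log space* over all points. The offset
\(d_0\) (cm) absorbs the distance between the gantry mouth (where \(d=0\)
is measured) and the effective source centre inside the bore; fitted values
near 50 cm are physically sensible, and fitted exponents near 3 match the
dipole-like far-field decay of a coil. A plain two-point log–log
interpolation without offset does not reproduce the packaged survey
clearances; the offset model does.

Numerically, the fit profiles out the linear parameters (\(\log A\), \(n\))
exactly for fixed \(d_0\) and searches \(\log d_0\) over \([10^{-3},
10^4]\) cm with a deterministic one-dimensional optimizer (tolerance
\(10^{-12}\) in log space). Three points are interpolated exactly — the
offset is the root of a slope-matching equation, found by bisection to
\(10^{-13}\) — so three-point fits pass through the data to better than
\(10^{-9}\) relative in log space. Degenerate profiles (equal indices, or
increasing with distance) are rejected with an explicit error.

The **clearance** is the solution of \(I(d) = 100\%\):
\(d^\* = (A/100)^{1/n} - d_0\), clipped at zero, with a
`compliant_everywhere` flag when even the gantry-mouth value is compliant,
and an `extrapolated` flag when the crossing lies outside the sampled range.
The survey literature reports clearances with a ±3 cm uncertainty without
stating the recipe; this package adopts, as its own convention: half-range
of leave-one-out refits for profiles with at least four points, and
half-range of crossings under ±5% perturbation of each index (one at a
time) for three-point profiles. On the packaged profiles this yields ±1.9,
±1.3 and ±0.7 cm — consistent with, and tighter than, the published ±3 cm.

Applied to the packaged survey tables (computed by `scripts/acceptance.R`
and the test suite), the fits give 91.3 cm and 82.1 cm for the Ingenia B2
profiles at 100 cm and 160 cm height, against published values of 91 ± 3 and
83 ± 3 cm. The four-point Magnetom Aera C2 profile gives 100.9 cm (100.0 cm
if the 150 cm point is excluded) against a published 104 ± 3 cm; the printed
profile itself contains an index of exactly 100% at 100 cm, so any fit
through the printed (rounded) values must cross very near 100 cm — the
published 104 was evidently computed from unrounded instrument data, which
is not public. The package reports what the printed data support.

**Threshold semantics.** Compliance is \(I \le 100\): ties are compliant,
matching the "less than or greater than 100" reading of the index.

## Zoning

`classify_zone()` implements the EN 50499 Annex E ladder: Zone 0 if the RL
index is ≤ 100%, else Zone 1a if the low-AL index is ≤ 100%, else Zone 1b if
the high-AL index is ≤ 100%, else Zone 2. Inputs are expected ordered
RL ≥ low AL ≥ high AL (true for the curves at every frequency); measured
triples occasionally violate this by probe-reproducibility error, which
produces a warning, not an error. `zone_boundary_map()` turns per-curve
profiles of one transect into ordered boundary distances (the RL crossing is
the Zone 0 / Zone 1a boundary, and so on). The output labels distances along
the measured departure line; it deliberately performs no 2-D interpolation
across the room, which a single transect cannot support.

## Problem sizes and runtime choices

The test suite generates everything it needs at run time: tones and trains
of 10–20 periods at 32–128 kHz sampling (a few thousand samples), 50 random
single tones for the closed-form check, 100 seeded noisy profiles for the
clearance-recovery study, and a 10⁶-point brute-force time scan as the
independent oracle for the superposition test. These sizes make every
property estimate stable to well within its asserted tolerance while the
whole suite runs in seconds.

## Known limitations

* The spectral back end assumes a discrete line spectrum; continuous-spectrum
  noise input should use the time back end.
* The cascade phase model is one canonical realisation of a weighting
  filter; real instruments differ in corner placement and order, so
  instrument emulation is approximate by nature.
* The offset power law is a single-term model; very close to the coils or
  behind the magnet the field is not a single effective source and the fit
  should be restricted to the line of interest.
* Uncertainty on the clearance reflects refitting variability only, not the
  calibration uncertainty of the underlying index measurements.
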