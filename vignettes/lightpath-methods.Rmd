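---
title: "Modelling fluorescence light paths: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fluorescence light paths: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightpath)
```

## The model

A fluorescence channel is a chain of spectra. The excitation source with
intensity $I(\lambda)$ passes the excitation-path optics with combined
transmission $X(\lambda)$ and is absorbed by the dye in proportion to its
absorption spectrum $A(\lambda)$; the dye re-emits with spectrum
$E(\lambda)$, which passes the emission-path optics $M(\lambda)$ and is
registered by a detector with quantum efficiency $Q(\lambda)$. The package
reports three numbers per setup:

$$
\mathrm{ex} = \frac{\int I\,X\,A \,d\lambda}{\int I \,d\lambda},
\qquad
\mathrm{em} = \frac{\int E\,M\,Q \,d\lambda}{\int E \,d\lambda},
\qquad
B = 10\,\cdot\,\mathrm{ex}\cdot\mathrm{em}\cdot
    \frac{\mathrm{EC}\cdot\mathrm{QY}}{73000 \times 0.92}.
$$

The brightness normalisation is chosen so that a dye with the reference
photophysics (extinction coefficient $73000\ \mathrm{M^{-1}cm^{-1}}$,
quantum yield $0.92$ — the constants of Alexa 488) scores exactly 10 when
both efficiencies are 1. `scripts/acceptance.R` recomputes this calibration
end-to-end.

Three physical assumptions are baked in and matter for interpretation:

1. **Lossless optics.** A filter used in reflection contributes
   $R(\lambda) = 1 - T(\lambda)$. Real coatings absorb a little; the model
   slightly flatters reflection-mode dichroics.
2. **Absorption-spectrum excitation.** The absorbed fraction is the
   peak-normalised absorption spectrum times the (filtered) source. This is
   accurate near the absorption peak; far from it, other transitions make
   the model an overestimate.
3. **Brightness $\propto$ EC·QY.** Extinction coefficients are measured at
   peak absorption and quantum yields depend on the local environment, so
   brightness is a comparative score, not an absolute photon count.

Out of the model's scope, deliberately: photostability, illumination
intensity, objective collection (NA), and detector noise. Brightness ranks
dyes and setups; it does not predict detectability.

## Numerical scheme

**Grid and interpolation.** All arithmetic happens on a 1 nm integer grid.
Operands of a product are linearly interpolated onto the grid spanning the
union of their measured ranges, clamped to 200–1000 nm, and every spectrum
is taken to be exactly zero outside its own measured range. The familiar
300–800 nm plot window is display-only; computations always use the full
range of the data.

**Integration.** Areas are trapezoidal sums on the 1 nm grid — exact for
the piecewise-linear interpolant the resampling step defines, so the engine
agrees with a dense (0.01 nm) brute-force Riemann integration of the same
interpolants to float precision; the test suite asserts agreement within
$10^{-6}$ relative over 50 randomised synthetic setups. Whether a rectangle
or trapezoid rule better matches other implementations of this model is
unknowable from outside; the difference is below the reporting precision.

**Shared grids inside a ratio.** Each efficiency evaluates its numerator
and denominator on one common grid. This is deliberate: the zero-extension
ramp that the interpolant carries at a spectrum's first and last sample
(half a sample's worth of area per edge) then cancels between numerator and
denominator instead of biasing the ratio. It is also what makes the ideal
reference setup score exactly 10 rather than 10 ± a boundary artefact.

**Unit handling.** Vendor curves ship both as fractions (0–1) and percent
(0–100). Any transmission/reflection/qe/absorption/emission column with a
value above 2 is treated as percent and divided by 100. The threshold 2
cleanly separates the conventions: genuine fractional curves cannot exceed
1, and percent curves of interest exceed 2 somewhere.

**Peak-normalised absorption.** Dye absorption is normalised to 1 at its
maximum when a dye is constructed, so "fraction absorbed" equals 1 at the
absorption peak under assumption 2. Emission is left at its supplied scale:
collection efficiency is a ratio of areas, so any scale cancels.

**Complement outside the measured range.** The lossless complement is only
defined where transmission was measured. A reflection-mode filter therefore
contributes zero — is opaque — outside its measured range, never a
fabricated perfect reflector. This is the conservative choice: it can
understate, never overstate, a stack's throughput.

**Degenerate inputs.** A single-sample spectrum (the laser model) is a
1 nm-wide triangular pulse under zero-extension, with area equal to its
value. Empty spectra, non-ascending wavelengths, negative values and
above-unity transmissions are rejected at construction with located errors.
A missing detector means unit quantum efficiency, and the report says so.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| reference EC | 73000 M⁻¹cm⁻¹ | brightness normalisation (Alexa-488-like) |
| reference QY | 0.92 | idem |
| brightness scale | 10 | multiplier on the normalised score |
| working-grid clamp | 200–1000 nm | hard bounds of any computation grid |
| plot window | 300–800 nm | display only |

The reference constants are fixed by convention and should only be changed
(via `reference_constants()`) when comparing against scores produced under
a different normalisation.

## What the synthetic generators emulate

The generators produce the idealised shapes that component collections for
this kind of model typically contain, deterministically (identical
arguments give byte-identical files):

- `gaussian_dye()` — unit-peak Gaussian absorption and emission sampled over
  $\mu \pm 5\sigma$, with an enforced positive Stokes shift. Real dye
  spectra are asymmetric with vibronic shoulders; Gaussians keep every
  expectation computable in closed form (e.g. a laser one $\sigma$ off-peak
  excites with efficiency $e^{-1/2}$).
- `box_filter()` — band-pass with `t_pass` strictly inside the band,
  `t_stop` outside, and the 50% point sampled exactly at the stated cut
  wavelengths. Filter edges are conventionally specified by their
  half-transmission wavelength, and sampling the edge at half height makes
  1 nm band integrals agree with ideal-edge closed forms to second order
  (the suite checks $\Phi(1.5)-\Phi(-0.5)$ to $10^{-3}$) instead of
  carrying a half-sample bias of roughly 1%.
- `edge_dichroic()` — logistic long-pass edge, 50% at the cut wavelength.
- `laser_line()` — the 1 nm unit pulse described above.
- `flat_lamp()`, `flat_detector()` — constants over a stated range.

What passing tests on these fixtures shows: the integration pipeline, mode
handling, normalisation and ranking logic are correct for well-behaved
inputs. What they do not show: robustness to the noise, digitisation
artefacts, baseline offsets and asymmetries of real vendor curves — those
enter through the same file reader and resampler, but their spectra are not
represented by the generators. The `validate` CLI command exists to triage
such files.

## Design choices that were genuinely open

- **Sizes used in the randomised suites.** 50 randomised setups for
  oracle-equivalence and monotonicity and 100 files for round-trip checks
  give each property broad coverage of the parameter ranges while the whole
  suite stays interactive (seconds, not minutes).
- **Ranking ties.** `optimise_dyes()` sorts by brightness descending with
  ties broken by dye id ascending, so rankings are deterministic and stable
  across platforms. Dyes lacking EC or QY are kept with their efficiencies,
  flagged, and sorted last rather than dropped — a dye without constants is
  still informative for band placement.
- **Setups schema.** Setups are a JSON array of
  `{name, excitation, dye, detector, ex_path, em_path}` with
  `{filter, mode}` path entries; plain `"ID MODE"` strings are accepted as
  a permissive fallback. Duplicate setup names and unknown modes are
  errors; the same filter id may appear in both paths with opposite modes
  (a shared dichroic) or twice in one path (double-pass, intentionally
  squared).
- **Numeric serialisation.** Files are written with up to 15 significant
  digits, the most a decimal string can carry and still round-trip through
  a double exactly; write → parse → write is byte-identical.
- **Exit codes.** The CLI distinguishes usage errors (2) from data errors
  (3) so shell pipelines can tell a typo from a broken collection.

## Known limitations

- Angle-of-incidence and polarisation dependence of dichroics are ignored;
  spectra are taken as scalar transmissions.
- Only one dye per setup: multi-channel questions are composed from
  multiple setups, and bleedthrough is estimated as the brightness ratio of
  the off-target dye to the channel's own dye in the same setup.
- Efficiencies saturate at 1 by construction; values within float epsilon
  of 1 are clamped.
- The percent heuristic misclassifies a hypothetical fractional spectrum
  scaled above 2, and a percent curve everywhere below 2% — both
  pathological for real optics data.
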