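---
title: "Methods: two-layer Monte Carlo inversion for SFDI of pigmented skin"
author: "twoLayerSFDI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer Monte Carlo inversion for SFDI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spatial frequency domain imaging (SFDI) projects sinusoidal illumination at
two spatial frequencies (here 0 and 0.1 mm^-1) and converts the
frequency-dependent attenuation into wide-field maps of tissue absorption
(mu_a) and reduced scattering (mu_s'). Its shallow interrogation depth makes
it attractive for monitoring hemodynamics of superficial breast tissue, but
the same shallowness makes the recovered properties highly sensitive to
melanin in the epidermis. A homogeneous inverse model attributes epidermal
melanin absorption to the bulk tissue and, for strongly pigmented skin,
returns physiologically impossible hemoglobin values. This package
implements a two-layer inverse model in which the epidermal absorption is a
free parameter estimated from the data themselves, plus everything needed to
validate it end to end on software phantoms.

## Transport model

Tissue is modelled as a plane-parallel two-layer medium: a thin, non-perfused
epidermis (model thickness `depi = 0.011` cm) whose only chromophore is
melanin, over a "subcutaneous" layer (dermis + subcutis, 10 cm thick — about
40 transport mean free paths, i.e. effectively semi-infinite) whose
chromophores are oxy- and deoxyhemoglobin. All layers share anisotropy
`g = 0.8` and refractive index `n = 1.4`; the ambient index is 1. The full
scattering coefficient is recovered from the reduced one through the
similarity relation `mu_s = mu_s' / (1 - g)`.

Photon transport (`runWhiteMC`) is *white* Monte Carlo: a collimated pencil
beam enters at the origin and photons are traced with `mu_a = 0`,
Henyey-Greenstein scattering, unpolarized Fresnel reflection/escape at the
top surface and index-matched internal interfaces. For every photon escaping
the top surface the exit radius and the pathlength spent in each layer are
recorded. Any absorption pair is then applied after the fact by Beer-Lambert
weighting, so one simulation serves the whole absorption grid. Reflectance
is scored natively in the spatial frequency domain
(`scoreSFD`): each exit record contributes
`w * exp(-sum(mu_a,k L_k)) * J0(2 pi fx rho)`, which is exact for the
radially symmetric pencil-beam response under one-dimensional sinusoidal
illumination and avoids radial binning artifacts.

Numerical/termination choices (the source method leaves these open, so they
are declared here):

* photons crossing the bottom of the deepest layer are lost;
* a photon whose pathlength can no longer stay below `maxPathlength`
  (default 450 cm) is terminated: at the smallest tabulated absorption
  (0.01 cm^-1) the largest neglected Beer factor is `exp(-4.5) ~ 1e-2`
  carried by well under 3% of photons, which biases scored reflectance by
  less than 0.1% (measured: ~0.01% at mu_a = 0.01 cm^-1) while capping the
  very long random walks that otherwise dominate run time;
* Russian roulette (threshold 1e-4, survival 0.1) is implemented for
  generality; with probabilistic Fresnel escape the white-MC weight stays at
  1 minus the specular loss, so roulette effectively fires only in the
  companion absorbing simulation;
* the RNG is a per-run xoshiro256++ stream seeded through splitmix64 —
  bit-identical results for identical seeds, independent of R's RNG, with
  the seed stored in the table provenance.

`runDirectMC` is a deliberately separate implementation that applies
absorption during flight (albedo weighting); it serves as the independent
cross-check that white MC + rescaling is unbiased (the suites require
agreement within 3 combined standard errors).

## Lookup tables and inversion

`buildDeviceLUTs` runs one two-layer simulation per (wavelength,
subcutaneous scattering) pair — epidermal scattering fixed at 22.16, 16.89
and 11.62 cm^-1 for 662, 735 and 859 nm — and fills a
21 x 75 x 17 grid per wavelength: `mu_a,epi` 0-20 cm^-1 (21 values),
`mu_a,sub` 0.01-0.75 cm^-1 (75 values), `mu_s,sub'` 4-20 cm^-1 (17 values),
all linearly spaced. The Beer rescaling is organized as two matrix products
per record set, so grid filling is BLAS-bound. A conventional homogeneous
table (75 x 17) is built the same way from single-layer runs; since white MC
knows nothing of wavelength, one homogeneous record battery serves all
three wavelengths.

`collapseLUT` interpolates linearly along the `mu_a,epi` axis only,
reproducing exact slices at the nodes, and yields a conventional
two-frequency table. `invertRd` inverts it by piecewise-linear interpolation
over the two-triangle split of each forward-grid cell in (Rd(0), Rd(0.1))
space — the structured-grid specialization of scattered-data triangulation.
It is exact at grid nodes; queries outside the forward gamut are clamped to
the nearest gamut-boundary point and flagged (never silently extrapolated),
so dynamic movies remain processable while a per-pixel quality mask records
the clamps.

## Calibration chain

`demodulate` uses the symmetric three-phase identities
`M(0) = (I1 + I2 + I3)/3` and
`M(0.1) = sqrt(2)/3 * sqrt((I1-I2)^2 + (I2-I3)^2 + (I3-I1)^2)`;
the symmetric form recovers the amplitude of an ideal sinusoid exactly at
any phase offset, which the property suite exercises with random
(B, A, phi). Calibration divides by the demodulated reference-phantom stack
and multiplies by the phantom's theoretical reflectance, which is computed
from the homogeneous table after carrying the phantom characterization
(mu_s' of 7.1 and 5.3 cm^-1 at 690 and 830 nm; mu_a averaged to
0.0495 cm^-1) to the device wavelengths with the scattering power law
`mu_s'(lambda) = A (lambda/lambda0)^-b`, `lambda0 = 735` nm. Projector
profile and flat-field effects are assumed to cancel in the ratio.
Saturated pixels are masked before demodulation; blank marker frames (mean
below 5% of the stack median) locate the sequence start in raw recordings.

## Melanin index and its optimization

Epidermal thickness and absorption are strongly coupled in diffuse
reflectance, so the model estimates only their product, the melanin index
`MI = depi * mu_a,epi(662)` — the approximate epidermal optical thickness at
662 nm. Melanin is assumed to be the sole epidermal absorber with extinction
`exp(-0.009 lambda + 12.93)`, which ties the three wavelengths to one degree
of freedom: `mu_a,epi(lambda) = (MI/depi) exp(-0.009 (lambda - 662))`.

`optimizeMI` scans 161 evenly spaced MI values on [0, 0.176]
(`mu_a,epi(662)` from 0 to 16 cm^-1): for each candidate it collapses the
tables, inverts the measured reflectance, and unmixes the recovered
`mu_a,sub(lambda)` into hemoglobin concentrations by unconstrained least
squares against a compiled extinction tabulation (`mu_a = ln(10) eps C`).
The fit quality is `MSE = mean(e_lambda^2)`; the selected MI minimizes MSE
("mse" mode — appropriate for two-chromophore simulated data) or
`MSE / (1 - StO2)` ("adjusted" mode — the in-vivo variant that counteracts
the bias toward near-zero deoxyhemoglobin caused by chromophores the
three-wavelength fit cannot represent). The adjusted criterion is +Inf
wherever StO2 >= 1, which operationalizes "undefined" and excludes those
candidates from the argmin; exact ties resolve to the smallest MI.
Candidates whose inversion leaves the table gamut at any wavelength are
likewise excluded: a hull-clamped inversion is not a valid solution, and
treating it as one lets coincidentally self-consistent clamped spectra
masquerade as perfect hemoglobin fits (a table lookup that simply returns
no value — as a bounded interpolation would — behaves the same way).
Concentrations are deliberately not constrained to be positive — unphysical
fits are flagged, not hidden. Per-subject MI is averaged across
measurements (mean, not median) when several are available.

## Dynamic processing

Compression measurements (1 min baseline, 1 min at target pressure, 1 min
recovery; one frame every 2 s) are processed pixelwise:

* *Specular rejection:* a pixel whose M(0) deviates from the per-frame image
  mean by more than 2.5 SD at any wavelength or timepoint is excluded
  throughout. Per-frame statistics are used because this criterion is
  phrased per image.
* *Baseline averaging:* mean reflectance over retained pixels and the
  closed window t in [10, 55] s (the first 10 s absorb repositioning) feeds
  the MI optimization. All window endpoints in the package are closed;
  boundary frames are included.
* *Dynamic rejection:* after inversion, a pixel whose `mu_a,sub` deviates by
  more than 8 SD from a ~20 mm central square's statistics (pooled over
  time, per wavelength) is excluded.
* *ROIs:* the circular field of view is split into eight equal-area
  45-degree sectors numbered clockwise from image-up (the source layout is
  unspecified; sectors are symmetric and simple, and a 2 x 4 grid is
  available as an alternative). An ROI is dropped when rejected pixels
  exceed 60% of it (strictly), when its baseline StO2 slope exceeds
  0.045 pp/s in magnitude, or when the RMS deviation from the baseline fit
  exceeds 0.4 pp. Compression slopes are fitted over t in [65, 113] s.
  StO2 is stored as a fraction and converted to percentage points at the
  fitting boundary.

## Synthetic data

The generator produces everything the pipeline consumes, with ground-truth
sidecars: forward-simulated phantom reflectance (`makeForwardRd`), raw
three-phase stacks whose demodulation + calibration reproduce the target
reflectance exactly in the noise-free limit (`makeRawStack`), and
compression movies (`makeCompressionMovie`) in which total hemoglobin
follows a raised-cosine blanching dip (20 uM baseline, 4 uM dip by default,
minimum mid-compression), StO2 follows a linear compression trend
(-0.011 pp/s by default, the magnitude scale reported for healthy breast,
with 0.004 pp/s per-ROI jitter), and two smooth static fields modulate the
maps: a 2% heterogeneity field on tHb (physiological texture) and a 2%
multiplicative field on the reflectance itself (the residual spatial
structure — tissue texture, curvature, flat-field remnants — that
calibrated in-vivo reflectance images carry). The second field matters for
realism of the artifact rejection: the per-frame SD criterion is selective
only when static spatial structure dominates frame noise, as it does in
real images; on a perfectly flat synthetic field, temporal noise alone
would eventually trip the threshold at some frame for nearly every pixel. The default software-phantom battery uses the study
conditions: MI in {0, 0.005, 0.01, 0.04, 0.07, 0.1, 0.13, 0.16},
`depi = 0.011` cm, `mu_s,sub'` = 10.21/8.94/7.78 cm^-1, tHb = 20 uM,
StO2 = 75%.

Noise defaults (0.5% signal-proportional, 0.1% full-scale additive,
optional specular discs and drift) are declared presets for realism, not
derived from any characterization; validation batteries run noise-free so
that Monte Carlo counting noise is the only stochastic component. The
generator shares the forward tables/engine with the inverse model, so
closed-loop tests demonstrate self-consistency of the implementation — they
cannot detect model error that real tissue would introduce (curvature,
texture, extra chromophores, pressure-dependent optics), which is exactly
the gap the adjusted-MSE mode exists to absorb.

## Validation suite and problem sizes

`reproduceValidation` re-runs the full software-phantom study: matched-table
round trip (max property error), MI-optimized layered recovery (mean signed
tHb/StO2 errors), homogeneous-model comparison, and the mismatch batteries
(epidermal thickness 0.003-0.019 cm in nine steps with `mu_a,epi` co-varied
to preserve MI; epidermal scattering amplitude and power each scaled by
+/-10/20/30%, the power anchored at 735 nm). Record sets are cached by
geometry so each distinct medium is simulated once and re-weighted across
melanin levels.

Photon budgets follow an importance allocation: the scattering nodes that
bracket the device's subcutaneous scattering (7-11 cm^-1) carry a denser
budget than the outer nodes, which only shape the inversion gamut, and the
three matched forward phantoms — whose noise enters every error statistic —
are run longest. Defaults are 2e5 photons per outer and 4e5 per dense
lookup-table run, 6e5 per matched forward phantom and ~1e5 per mismatch
phantom (the mismatch batteries need roughly this much for their max-error
statistic to reflect model mismatch rather than counting noise); the unit
fixtures use a coarser in-suite table at reduced counts. The tables ship
with their photon counts and seeds in the provenance block, and larger
builds are a single argument away.

Two behaviors of the validation suite are worth knowing. First, the
headline recovery statistics are Monte Carlo estimators: with the default
budgets the mean signed StO2/tHb errors of the MI-optimized layered model
fluctuate by roughly +/-1.5 percentage points between seeds, because the
argmin of a shallow MSE valley shifts by a few grid steps under table and
phantom counting noise. Second, at the extremes of the epidermal
thickness-mismatch battery (+/-70% of the model thickness) combined with
high melanin, the three-wavelength optimization leaves a systematic
residual of up to ~15-19% in StO2 (positive for a thinner-than-model
epidermis, negative for thicker); within +/-40% thickness mismatch and for
all scattering mismatches the errors stay in the single digits. Both are
properties of the estimator itself, not of any particular run.

## Known limitations

* Two layers only; dermis and subcutis are merged, and partial-volume
  effects of any target lesion are not modelled.
* Water and lipid are not fitted; with only three wavelengths their
  signature is aliased into hemoglobin, which is why the adjusted-MSE mode
  exists and why it remains an ad-hoc correction.
* The melanin-index estimate loses sensitivity at low pigmentation (the
  MSE valley flattens as MI -> 0).
* No polarization, fluorescence, time-resolved transport, curved surfaces
  or index-mismatched internal interfaces; more than two spatial
  frequencies and tables parameterized by g or n are out of scope.
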