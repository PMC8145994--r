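# twoLayerSFDI

Two-layer Monte Carlo lookup-table inversion for spatial frequency domain
imaging (SFDI) of tissue under variable skin pigmentation, with the full
processing chain for dynamic breast-compression measurements.

## The problem

SFDI projects sinusoidal illumination at two spatial frequencies
(fx = 0 and 0.1 mm⁻¹, three phase shifts each) at 662, 735 and 859 nm,
demodulates the reflected images and converts the diffuse reflectance pair
(R_d(0), R_d(0.1)) into absorption μ_a and reduced scattering μ_s′ maps.
Because the method interrogates only the first few millimetres of tissue,
melanin in the epidermis contaminates the recovered properties: a
homogeneous inverse model applied to strongly pigmented skin returns
physiologically impossible hemoglobin values (errors of order 100–200% in
StO₂ and total hemoglobin at high melanin). This package is written for
researchers in diffuse optics who need subcutaneous hemodynamics —
oxy-/deoxyhemoglobin concentration, total hemoglobin tHb and saturation
StO₂ = HbO/tHb — that remain valid across skin tones.

## The model

Tissue is a two-layer medium: a thin epidermis (model thickness
d_epi = 110 μm, fixed scattering per wavelength, melanin its only absorber)
over an effectively semi-infinite "subcutaneous" layer whose absorption is
set by hemoglobin. A layered *white* Monte Carlo engine (pencil beam,
Henyey–Greenstein g = 0.8, n = 1.4, Fresnel surface, μ_a = 0, per-layer
pathlengths L_k recorded) scores reflectance natively in the spatial
frequency domain,

    R_d(fx) = (1/N) Σ w · exp(−Σ_k μ_a,k L_k) · J₀(2π fx ρ),

so one simulation serves an entire absorption grid via Beer–Lambert
rescaling. Per wavelength this yields a 21 × 75 × 17 lookup table over
μ_a,epi ∈ [0, 20] cm⁻¹, μ_a,sub ∈ [0.01, 0.75] cm⁻¹ and
μ_s,sub′ ∈ [4, 20] cm⁻¹. The epidermis enters through a single degree of
freedom, the melanin index

    MI = d_epi · μ_a,epi(662),    μ_a,epi(λ) = (MI/d_epi) · e^(−0.009(λ−662)),

and MI is estimated per subject by scanning 161 candidates on [0, 0.176]:
for each, the table is collapsed at the implied μ_a,epi(λ), the measured
R_d pair inverted, and the recovered μ_a,sub(λ) unmixed into hemoglobin by
least squares against extinction coefficients; the selected MI minimizes
the spectral-fit MSE (or MSE/(1 − StO₂) for in-vivo data). Dynamic
compression movies are then processed pixelwise at the fitted MI into
per-ROI tHb(t)/StO₂(t) traces with artifact and baseline-stability
screening.

## Worked example

Forward-simulate a pigmented software phantom (MI = 0.1, tHb = 20 μM,
StO₂ = 75%), then recover the melanin index and hemodynamics with a small
table set:

```r
library(twoLayerSFDI)

luts <- buildDeviceLUTs(nPhotons = 5e4, seed = 3)   # ~4 min on one CPU
rd   <- makeForwardRd(phantomSpec(0.1), nPhotons = 5e4, seed = 11)
rd
#> SfdReflectance at fx = {0, 0.1} mm^-1
#>  wavelength       rd0       rd1
#>         662 0.4120215 0.1780377
#>         735 0.5454952 0.1856087
#>         859 0.6066661 0.1752789

optimizeMI(rd, luts$twoLayer)
#> MIFitResult: MI = 0.1034 selected by mse over 161 candidates
#>   tHb = 19.46 uM, StO2 = 78.1%, MSE = 8.39e-11 cm^-2
```

The reflectance triplet falls with wavelength-dependent melanin absorption
(strongest at 662 nm); the optimizer recovers the planted MI to a few grid
steps and hemoglobin to a few percent with this small demonstration table
(5 × 10⁴ photons/node — production tables use 2–4 × 10⁵). Inverting the
same phantom with the homogeneous table instead illustrates the failure
mode the layered model exists to fix:

```r
inv <- invertRd(refineLUT(luts$homogeneous), rd@rd0, rd@rd1)
fitHemoglobin(inv$mua)[c("tHb", "stO2")]
#> $tHb
#> [1] 48.02676
#> $stO2
#> [1] 0.09918113
```

tHb inflated 2.4-fold and StO₂ collapsed from 75% to 10% — melanin
absorption read as deoxyhemoglobin.

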