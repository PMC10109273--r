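---
title: "Designing and pulsing tissue-mimicking phantoms with pulsephantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and pulsing tissue-mimicking phantoms with pulsephantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsephantom)
```

## The problem

Optical instruments for photoplethysmography (PPG) — pulse oximeters,
wearable heart-rate sensors — are developed and quality-controlled against
tissue-mimicking phantoms: layered elastomer slabs that reproduce the
optical and mechanical properties of skin and carry artificial blood
vessels that can be made to pulse. Building such a phantom poses four
quantitative design problems, and `pulsephantom` implements the full chain:

1. **Mechanics.** PDMS stiffness is tuned by the curing-agent fraction.
   From tensile tests we extract Young's modulus as the stress–strain slope
   in the linear-elastic region, fit the linear modulus-vs-concentration
   calibration, and invert it to formulate a layer at a target vessel
   stiffness.
2. **Pulsation.** Given an arterial pressure pulse, how far does the vessel
   wall move? The vessel is a thick-walled isotropic cylinder; Lamé theory
   gives the answer in closed form.
3. **Pump control.** Piezo micropumps drive the flow; channel expansion is
   linear in drive amplitude. Calibrating that line and inverting it turns
   a target wall-displacement waveform into a discretised pump-voltage
   sequence.
4. **Optics.** Absorbing and scattering dopants (synthetic melanin, India
   ink, TiO2) are mixed into the PDMS so that the layer's absorption and
   reduced scattering spectra match tissue. Finding the concentrations is a
   non-negative least-squares problem over the wavelength grid.

A fifth, supporting leg measures channel diameters (and hence expansions)
from microscope images by sub-pixel analysis of gray-value profiles, and a
seeded synthetic-data module generates every input the pipeline consumes so
that all of the above is testable without instruments.

## Mechanics: modulus extraction and formulation

Young's modulus is the OLS slope of stress on strain restricted to the
0–5% strain window (`fit_youngs_modulus()`); at least three in-window
points are required. Modulus vs curing-agent concentration is fitted as an
OLS line with free intercept (`fit_elastic_calibration()`); the bench data
this emulates are strongly linear (reported R² of 0.99), so no higher-order
model is entertained. Formulation inverts the line,

$$c = (E - b)/a,$$

and reports the concentration rounded half-up to one decimal, the precision
at which formulation tables are printed; full precision is kept internally.
Inversions outside the calibrated concentration range warn rather than
fail, because realistic targets for the softest vessels sit slightly below
the softest tested mix.

```{r}
plain <- elastic_calibration(slope = 0.18, intercept = -0.39)
invert_calibration(1, plain)$reported     # artery-stiffness layer, % curing agent
invert_calibration(0.37, plain)$reported  # capillary-stiffness layer
```

A known quirk of the underlying bench table: inverting the printed plain
PDMS line at the arteriole modulus of 0.12 MPa gives 2.8%, while the table
prints 2.3% — almost certainly unrounded coefficients upstream. The package
reports what the printed line implies and does not special-case it.

## Pulsation: thick-walled-cylinder displacement

All quantities are differential, relative to the diastolic baseline, and
the external pressure on the vessel is taken as zero (the surrounding
layer is three orders of magnitude softer than the wall). For a transmural
pressure change $\Delta p$, the interior-surface stresses are

$$\Delta\sigma_r = -\Delta p, \qquad
\Delta\sigma_\psi = \Delta p\,\frac{r_i^2 + r_o^2}{r_o^2 - r_i^2}, \qquad
\Delta\sigma_z = 2\nu\,\Delta p\,\frac{r_i^2}{r_o^2 - r_i^2},$$

Hooke's law gives the hoop strain
$\Delta\epsilon_\psi = [\Delta\sigma_\psi - \nu(\Delta\sigma_r +
\Delta\sigma_z)]/E$, and the radial displacement is
$u = \Delta\epsilon_\psi\, r_i$, available in closed form via
`radial_displacement()`. The package deliberately keeps **two independent
code paths** — the closed form and the stress-composition chain — and the
test suite asserts their agreement to $10^{-12}$ relative over 1000 random
geometries.

Parameter choices:

* **Poisson ratio** defaults to 0.5, the incompressible limit appropriate
  for elastomers and soft tissue; it is user-settable in
  `vessel_geometry()`. The source model leaves $\nu$ symbolic.
* **Young's modulus is constant**: real arteries stiffen as they distend
  (incremental modulus), a refinement the model explicitly omits.
* **Units** are fixed at construction: radii and displacements in µm,
  moduli in MPa, pressures in kPa; mmHg converts at 0.133322 kPa/mmHg at
  the I/O boundary only.

```{r}
geom <- vessel_geometry(500, 750, 1)  # 1-mm channel, 0.25-mm wall, E = 1 MPa
radial_displacement(geom, 1)          # um per kPa of transmural pressure
```

## Pump control: voltage sequences

Channel expansion is linear in pump drive amplitude, with no intercept
(zero drive, zero expansion), so `fit_pump_calibration()` fits through the
origin by default; a free-intercept diagnostic mode exists because the
bench fits' treatment of the intercept is not documented. The drive is
amplitude-modulated at a fixed 100 Hz operating frequency, carried as
metadata only.

`synthesize_voltage_sequence()` converts a displacement waveform into the
pump controller's discrete steps (50 ms default) by averaging displacement
over each bin — the mean is the default because the controller holds each
level for the full bin; sample-and-hold at the bin start is available.
Voltage requests outside the 0–250 Vpp hardware range are **clipped, not
rejected**, mirroring the driver electronics; the clip count is messaged
and attached to the result.

```{r}
pw <- gen_pressure_pulse()             # one cardiac cycle, 1 ms sampling
vs <- pulse_to_voltage(pw, geom, pump_calibration(0.26))
head(as.data.frame(vs), 4)
```

## Optics: dopant model, recipe solving, dispersion

The mixture model is additive and concentration-linear per channel,

$$\mu(\lambda) = \mathrm{baseline}(\lambda) + \sum_d c_d\,
\mathrm{coeff}_d(\lambda),$$

with structural role constraints: ink contributes no scattering, TiO2 no
absorption, melanin both (its absorption falling steeply with wavelength,
as in pigmented skin). Linearity without dopant–dopant interaction is the
minimal assumption consistent with combining single-dopant
characterisations into mixtures. Spectra are stored as reduced scattering
$\mu_s'$ in mm⁻¹ on a strictly common grid (canonically 500–1000 nm at
1 nm); cm⁻¹ values convert only under an explicit flag, grid mismatches are
errors, and `regrid_spectrum()` is the single deliberate interpolation
path. Each fitted dopant response carries its own plain-PDMS baseline
estimate; the mixture model needs a single baseline and uses the
elementwise mean of the three (identical when fitted noiselessly).

`solve_recipe()` minimises the stacked residual
$[\mu_a;\, w\,\mu_s']$ over non-negative concentrations via a
Lawson–Hanson NNLS solver written in-package (none ships with the base
stack); the tests check it against an exhaustive active-set enumeration.
Targets unreachable from above baseline simply leave a documented positive
residual — concentrations cannot be negative.

Refractive-index dispersion is fitted with the Sellmeier form
$n^2(\lambda) = 1 + \sum_i B_i \lambda^2/(\lambda^2 - C_i)$ by variable
projection: the $B_i$ are linear given the poles $C_i$ and solved by OLS,
while the $C_i$ are optimised by bounded L-BFGS-B from a deterministic
start grid. Two terms are the default — nine refractometer wavelengths
cannot robustly support six parameters under noise — and poles are
constrained safely below the working band.

## Imaging: sub-pixel diameter measurement

A channel appears as a dark band on a bright background. For each of
`n_lines` (default 11) evenly spaced pixel lines perpendicular to the
channel axis, `diameter_from_profile()`:

1. lightly smooths the profile (Gaussian, σ = 0.8 px) — symmetric, so it
   does not displace the half-depth crossings of a symmetric edge, but it
   stops pixel noise from extending or splitting the thresholded trough;
2. sets the background level at the 95th intensity percentile and the
   trough level at the 5th percentile *within a 31-px window around the
   global minimum* (a global 5th percentile sits in the background
   whenever the channel covers under 5% of the profile);
3. thresholds at the half-depth midpoint, requires exactly one
   below-threshold run (≥ 2 px; several runs raise an ambiguity error,
   none a detection error), and locates the two crossings by linear
   sub-pixel interpolation;
4. applies an analytic saturation correction: modelling each edge as an
   error function with scale σ (estimated from the 30%/70%-depth crossing
   separation) and trough saturation ρ = 2Φ(W/2σ) − 1, the corrected
   width is $W = W_{1/2} + 2\sigma\,\Phi^{-1}(\rho/2)$. For deep, sharp
   troughs ρ → 1 and the correction vanishes, so ideal profiles measure
   exactly; for a 10-px channel blurred at σ = 3 px it removes an
   otherwise ~1-px positive bias.

The estimate is invariant to global linear intensity rescaling by
construction. Radial expansion from an image series is **half** the
diameter change (`expansion_series()`), consistent with the radial
displacement convention of the cylinder model, and delegates to
`fit_pump_calibration()`.

## What the synthetic generators emulate — and what they do not

Every generator is deterministic under a fixed seed.

* `gen_stress_strain()`: exactly linear stress–strain with additive
  Gaussian noise. Real PDMS softens beyond a few percent strain; since the
  fit window ends at 5% strain this is not modelled.
* `gen_calibration_points()`: linear voltage–expansion with additive noise,
  clipped at zero expansion.
* `gen_pressure_pulse()`: a constructed parametric waveform — systolic
  log-normal lobe, reflected log-normal lobe, exponential diastolic runoff
  — with landmarks at the aortic-valve-opening foot (0.1 s), systolic peak
  (0.19 s) and dicrotic notch (0.4 s) in a 1-s cycle. The lobe-peak
  parameter and reflected-lobe amplitude are solved numerically (root
  finding on the analytic derivative, with the reflected amplitude set 30%
  above the tangency value) so the global maximum falls exactly on the
  systolic landmark and a genuine local minimum forms near the notch. The
  default amplitude is 5.33 kPa, a typical 40-mmHg adult pulse pressure;
  no printed value exists for the corresponding bench figure, so this is a
  one-time physiological choice. The generator is **not** a hemodynamic
  (Windkessel) model: wave-reflection physics, beat-to-beat variability
  and measured pulse shapes are out of scope, so green pulse tests
  establish correct *plumbing and landmark placement*, not physiological
  fidelity.
* `gen_dopant_spectra()`: concentration-linear spectra with multiplicative
  noise (instrument error scales with signal), built on smooth power-law
  responses with skin-like magnitudes. Real dopant spectra have structure
  (water features, particle-size effects) that a power law lacks; recipe
  tests therefore validate the solver, not any specific material.
* `gen_channel_image()`: coverage-antialiased dark band, optional Gaussian
  blur and additive noise. No illumination gradients, vignetting or debris
  — the measurement's robustness to those is untested by construction.

## Numerical choices and edge cases

* Half-up rounding for reported concentrations (base `round()` is
  banker's).
* Waveform grids must be uniform within 1 ns; binning requires the source
  grid to be at least as fine as the output step.
* Degenerate designs (identical concentrations or voltages), empty
  waveforms, inverted geometries ($r_o \le r_i$), all-zero responses and
  Sellmeier pole proximity ($\lambda^2 - C < 10^{-6}\,\mu m^2$) raise
  classed errors (`pulsephantom_invalid_input`,
  `pulsephantom_degenerate_design`, …) rather than propagating NaN.
* Image I/O is plain-text: ASCII PGM (P2) or CSV matrices. The
  pre-installed stack offers no PNG/TIFF decoder, and in-memory matrices
  (plus RGB arrays via Rec. 601 luma) are first-class inputs anyway.

## Known limitations

* Single-layer, isotropic, constant-modulus wall mechanics; no
  viscoelasticity, no fluid–structure interaction, no multi-layer walls.
* The dopant model has no interaction terms and no anisotropy handling;
  $\mu_s$ vs $\mu_s'$ labelling ambiguities must be resolved by the user at
  I/O (the package never converts silently).
* The diameter measurement assumes one approximately straight channel per
  image, darker than the background (an `invert` flag covers the opposite
  contrast).
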