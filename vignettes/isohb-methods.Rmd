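---
title: "Imaging hemoglobin concentration and scattering power at isosbestic wavelengths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging hemoglobin concentration and scattering power at isosbestic wavelengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Skin reflectance in the visible range is shaped by two things: absorption by
chromophores (hemoglobin in the dermal vasculature, melanin in the
epidermis) and scattering by the fibrous and cellular ultrastructure. Two
scalar summaries carry most of the physiology:

* **C~th~** — the total hemoglobin (blood) volume fraction of the dermis, in
  vol. %. It rises with angiogenesis and hyperemia.
* **b** — the *scattering power*, the exponent of the power-law wavelength
  dependence of the reduced scattering coefficient,
  $\mu_s'(\lambda) = a\,\lambda^{-b}$ ($\lambda$ in nm, $\mu_s'$ in
  cm^-1^). b falls when effective scatterer size grows (cell swelling,
  edema, collagen engorgement).

`isohb` maps both quantities per pixel from just four diffuse-reflectance
images taken at **isosbestic wavelengths of hemoglobin** — 420, 450, 500 and
585 nm — where oxy- and deoxyhemoglobin absorb equally, so the estimates are
independent of oxygen saturation. This matters because tissue oxygenation
varies strongly and independently of blood volume.

## The model

### Forward physics

The skin is modelled as two plane-parallel homogeneous layers: a 0.06 mm
epidermis whose absorption is set by the melanin volume fraction C~m~, over
a 4.94 mm dermis whose absorption is set by C~th~ (fully oxygenated blood by
default). Both layers share the same reduced scattering spectrum
$\mu_s'(\lambda) = a \lambda^{-b}$. For transport, $\mu_s'$ is converted via
the similarity relation $\mu_s = \mu_s'/(1-g)$ with $g = 0.9$
(Henyey–Greenstein), refractive index 1.4 against air. With these
conventions a typical skin amplitude $a = 6.3\times10^9$ and $b = 3$ give
$\mu_s'(500\,\text{nm}) = 50.4\ \text{cm}^{-1}$, the accepted magnitude for
skin; the nm/cm^-1^ convention must be kept in mind when supplying `a`.

Diffuse reflectance is computed with a weighted-photon Monte Carlo kernel of
the standard multi-layer (MCML) type: normally incident pencil beam,
specular deduction by Fresnel reflection at the top interface, free paths
sampled from the Beer–Lambert law on $\mu_t$, fractional weight deposition
at every collision, Henyey–Greenstein scattering, Fresnel internal
reflection at all interfaces, and Russian-roulette termination (threshold
1e-4, survival 0.1). All photons leaving the top surface at any angle count
as diffuse reflectance — the crossed-polarizer hardware of a reflectance
imager is emulated solely by excluding the specular component. Photons
leaving the bottom of the 4.94 mm dermis are terminated; at these
wavelengths and blood contents that loss is far below the Monte Carlo noise
floor. Roulette gains and losses are debited against the absorbed tally, so
`specular + diffuse + transmitted + absorbed = 1` holds exactly for every
run, while every tally remains unbiased.

### The empirical formulas

Per pixel, each band is reduced to an absorbance
$A(\lambda) = -\log_{10} R(\lambda)$, and the two parameters are read off
with fixed linear formulas

$$b = \alpha_0 + \alpha_1 A(420) + \alpha_2 A(450) + \alpha_3 A(500) + \alpha_4 A(585),$$
$$C_{th} = \beta_0 + \beta_1 A(420) + \beta_2 A(450) + \beta_3 A(500) + \beta_4 A(585).$$

The coefficients are obtained once by ordinary least squares over a
simulated training set: the full Cartesian grid of
a ∈ {5.3, 5.8, 6.3, 6.8, 7.3}×10^9^, b ∈ {2.90, 2.95, 3.00, 3.05, 3.10},
C~m~ ∈ {1, …, 10} vol. % and C~th~ ∈ {0.2, 0.4, 0.6, 0.8, 1.0} vol. % —
1250 states built on 25 distinct scattering spectra. No regularization and
no interaction terms: the formulas are deliberately the plainest possible
so that applying them per pixel is a dot product and the whole imaging
pipeline runs without further transport simulation.

```{r}
library(isohb)
lib <- chromophore_library()
records <- simulate_training_set(build_training_grid(),
                                 transport_config(n_photons = 1e5, seed = 1),
                                 lib)
model <- fit_regression(records)
model
```

### Why the training simulation is fast

Simulating 1250 states x 4 bands naively is 5000 transport runs. The
package instead exploits that all states sharing `(a, b)` have identical
scattering: per scattering spectrum and band one *scattering-only* photon
ensemble is run and the per-layer path lengths of every escaping photon are
recorded; the reflectance of each absorption combination then follows by
Beer–Lambert reweighting, $R = \langle w\,e^{-\mu_{a,e} L_e - \mu_{a,d}
L_d}\rangle$. This "white Monte Carlo" estimator is unbiased and is
cross-checked against the direct weighted simulation in the test suite
(`method = "direct"` is available on `simulate_training_set()`). Because
non-absorbing deep walks are long, photons are additionally rouletted on
their best-case Beer–Lambert weight (the lower envelope of the absorption
combinations), which preserves unbiasedness for every combination.

## Chromophore library

The hemoglobin extinction table bundled under `inst/extdata/` is a
**synthetic parametric reconstruction**, not a copy of a published
compilation: sums of Gaussian bands anchored at the standard landmark
features (Soret peaks near 414/430 nm, the oxyhemoglobin Q-band doublet at
542/577 nm, the deoxy band at 555 nm, trough magnitudes of ~2x10^4^
cm^-1^/M near 500 nm), with *exact* isosbestic crossings imposed at 420,
450, 500 and 585 nm. Magnitudes are on the tetramer convention (64,500
g/mol), and blood volume fraction converts to absorption with a whole-blood
hemoglobin concentration of 150 g/L (2.33 mM). Melanin follows the standard
melanosome power law $\mu_a = 1.70\times10^{12}\,\lambda^{-3.48}$ cm^-1^.
Consequences worth knowing:

* the oxygenation-invariance of the estimates is exact at the four working
  bands rather than merely within the ~10% tolerance of real compiled
  spectra — tests of that invariance are therefore conservative about
  *code* correctness but say nothing about residual oxygenation coupling
  with real filters and real hemoglobin;
* any analysis at wavelengths other than the four working bands uses the
  synthetic band shapes and should not be quoted against laboratory
  spectra.

A replacement CSV with measured values can be supplied via
`chromophore_library(path = ...)`; training and estimation must use the
same library, which the `grid_hash` provenance check enforces.

## Parameters that matter

| Parameter | Default | Units | Why this value |
|---|---|---|---|
| epidermis / dermis thickness | 0.06 / 4.94 mm | mm | canonical two-layer skin geometry; the training grid is simulated at exactly these |
| g (anisotropy) | 0.9 | — | typical soft tissue; enters only through the similarity conversion; results are reported for the g used |
| n (skin / phantom / ambient) | 1.4 / 1.33 / 1.0 | — | standard values; phantom slabs are aqueous |
| so2 | 1.0 | fraction | fully oxygenated blood; irrelevant at the isosbestic bands (tested property) |
| photons per band | 1e5 | — | ~0.3–1% relative error on reflectance; desk-scale training |
| roulette threshold / survival | 1e-4 / 0.1 | — | standard MCML termination |
| IMC convergence threshold | 0.005 | combined &#124;dR&#124;+&#124;dT&#124; | declared default; the slab inversion accepts a candidate only if the residual falls |

## Accuracy of the linear formulas

The linear map from four absorbances to (C~th~, b) is an approximation: the
training grid spans a decade of melanin content, over which absorbance
saturates nonlinearly. Measured at the default photon count on the default
grid, refitting leaves residuals of about 0.024 in b and 0.065 vol. % in
C~th~ overall; 96–99% of training states come back within ±0.05 in b, but
only 80–88% within ±0.1 vol. % in C~th~ — the C~th~ figure is limited by
the curvature of the forward map (it does not improve with more photons)
and is dominated by the extreme melanin rows of the grid. In the interior
of the grid (the regime of the phantom validation and of the imaging
scenarios) residuals are roughly half as large. Two practical consequences
follow. First, end-to-end recovery of b over scenes spanning the *full*
grid correlates with truth at about 0.85–0.91 under per-scene 1%
reflectance noise — the ceiling is the regression's own residual at the
(a, b) grid edges, not photon noise. Second, the curvature compresses
large excursions: a +50% step in true C~th~ from a 0.5 vol. % baseline is
read back as roughly +30%, so relative-change time courses preserve sign,
timing and ordering, but under-read large amplitudes. The package reports
training R² for both responses so a user can judge a refitted model.

## Synthetic data: what it emulates and what it does not

The generator produces phantom sets, image stacks and week-by-week time
courses entirely in silico:

* **Phantom sets** (`generate_phantom_set()`): n = 12 two-layer phantoms on
  a latin-hypercube design over the interior of the training grid
  (C~th~ 0.3–0.9 vol. %, b 2.92–3.08, a 5.8–6.8x10^9^, melanin analogue
  fixed at 1 vol. %), forward-simulated through the same two-layer geometry
  the model is trained on, with 1% multiplicative Gaussian reflectance
  noise (shot-dominated camera regime). A 1.0 mm aqueous (n = 1.33)
  single-slab reflectance/transmittance pair per band accompanies each
  phantom for the inverse Monte Carlo route.
* **Image stacks** (`generate_image_stack()`): scenes are piecewise-constant
  class maps (default 64x64, few classes) so each class needs one transport
  run per band; per-pixel noise and optional 8-bit quantization are applied
  on top; the white reference is an exact unit field. Hard-edged lesion
  disks only — the estimator is pointwise, so soft edges would add nothing
  testable.
* **Time courses** (`generate_timecourse()`): a schedule of weekly
  (C~th~, b) multipliers applied to a baseline scene; truth deltas are exact
  by construction.

None of this emulates curvature shading, specular glints, skin texture,
inter-week registration error, or filter bandwidth — all recognized error
sources for real acquisitions. Passing the synthetic recovery tests
therefore demonstrates correctness of the pipeline and conditioning of the
regression, not field accuracy on a mouse.

The layer-thickness sensitivity study (`thickness_sensitivity()`) perturbs
what the training fixes: it simulates a fixed interior state
(C~m~ 1 vol. %, C~th~ 0.4 vol. %, a 6.3x10^9^, b 3.00) at epidermis
thicknesses 0.005–0.06 mm and dermis thicknesses 3.5–4.94 mm and reports
relative estimation errors against the generating values. The C~th~ error
moves monotonically with epidermis thickness (thinner epidermis removes
melanin baseline absorbance, biasing C~th~), while dermis thickness in this
range is beyond the visible-light sampling depth and leaves no trend in
either parameter.

## Inverse Monte Carlo for slab phantoms

`invert_slab()` recovers (μ~a~, μ~s~') of a homogeneous slab from a
measured (R, T) pair by iterating the forward kernel: coordinate-wise
multiplicative updates driven by the signed mismatches (more scattering if
R is too low, less absorption if T is too low), accepted only when the
combined residual |ΔR| + |ΔT| falls, with step halving otherwise, until the
residual drops below 0.005. Every candidate is evaluated with the same
seed, so the objective is deterministic and the search cannot chatter
against Monte Carlo noise. The recovered μ~a~(585) converts to C~th~
through the known blood extinction (fully oxygenated), and the four-band
μ~s~'(λ) converts to (a, b) by the log–log least-squares fit — closing the
validation loop of estimated-versus-given values without any physical
phantom.

Degenerate inputs are diagnosed rather than iterated on: R + T ≥ 1 and
non-positive measurements are refused; non-convergence within the
iteration budget returns the best-so-far pair flagged `converged = FALSE`.

## Numerical choices and degenerate inputs

* Reflectances ≤ 0 in a simulated training state make absorbance undefined;
  such states are excluded with a warning, never clamped.
* Image pixels with zero white reference, non-positive ratio, or ratio > 1
  are flagged in `valid_mask` and excluded from ROI means; out-of-range
  estimates (negative C~th~, b outside [1, 4]) are retained but flagged.
* The per-wavelength and per-task random streams are split
  deterministically from one base seed (xoshiro256++ in the kernel), so
  every artifact is reproducible from its recorded seed; scene and phantom
  generators record their seeds in the objects they return.
* `fit_regression()` refuses rank-deficient designs naming the collinear
  columns; the estimator refuses a model whose `grid_hash` does not match
  the one declared for the stack.

## Problem sizes used in the shipped tests

The package's own test suite trains the full 1250-state design at 10^5^
photons per scattering spectrum and band, validates the 12-phantom set at
10^5^ photons per band, runs the thickness study at 10^5^ photons and the
50-scene recovery sweep at 2x10^4^; the acceptance script trains at 10^5^
and simulates phantoms at 10^5^.
These sizes keep a complete run at desk scale while holding the Monte Carlo
contribution to the error budget below the regression's own approximation
error.

## Known limitations

* The linear formulas extrapolate poorly outside the training grid; the
  phantom generator warns when asked for out-of-grid ranges.
* Melanin estimation is out of scope; C~m~ acts only as a nuisance variable
  the formulas must be robust to.
* Oxygen-saturation imaging (non-isosbestic bands) is not implemented.
* Shading and curvature correction are not implemented; ROIs are explicit
  user-supplied masks.
* Filter bandwidth is ignored: bands are treated as monochromatic lines.
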