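# isohb

Imaging total hemoglobin concentration and scattering power of skin from
multispectral diffuse reflectance at the isosbestic wavelengths of
hemoglobin (420, 450, 500, 585 nm).

## Who this is for

Biomedical-optics groups doing wide-field reflectance imaging of skin (or
skin-mimicking phantoms) who want per-pixel maps of

* **C<sub>th</sub>** — total hemoglobin (blood) volume fraction of the
  dermis, in vol. % (rises with angiogenesis/hyperemia), and
* **b** — the scattering power, i.e. the exponent of
  μ<sub>s</sub>′(λ) = a λ<sup>−b</sup> (falls with cell swelling, edema and
  fibrous engorgement),

from just four grayscale images, *independent of hemoglobin oxygen
saturation*: at isosbestic wavelengths oxy- and deoxyhemoglobin absorb
identically, so oxygenation cancels out of the estimates by design.

## The method in one paragraph

A weighted-photon Monte Carlo kernel (standard multi-layer MCML scheme)
simulates the diffuse reflectance of a two-layer skin model — a 0.06 mm
melanin-bearing epidermis over a 4.94 mm blood-bearing dermis, both sharing
μ<sub>s</sub>′(λ) = a λ<sup>−b</sup> — over the full grid of
a ∈ {5.3…7.3}×10⁹, b ∈ {2.90…3.10}, C<sub>m</sub> ∈ {1…10} vol. %,
C<sub>th</sub> ∈ {0.2…1.0} vol. % (1250 states, 25 scattering spectra).
Each state's four reflectances become absorbances A(λ) = −log₁₀ R(λ), and
ordinary least squares fits the empirical formulas

    b   = α₀ + α₁A(420) + α₂A(450) + α₃A(500) + α₄A(585)
    Cth = β₀ + β₁A(420) + β₂A(450) + β₃A(500) + β₄A(585)

Applying these per pixel maps a measured image stack to (C<sub>th</sub>, b)
images with no further simulation. The package also ships the inverse Monte
Carlo slab inversion used to obtain reference optical properties of
physical phantoms, and a synthetic-data generator (phantom sets, image
stacks, week-by-week time courses, layer-thickness sensitivity studies)
so the whole pipeline can be validated without any instrument.

## Worked example

Train the regression (a few minutes; the 1250-state grid reuses one
scattering-only photon ensemble per scattering spectrum and band), then
image a synthetic lesion scene:

```r
library(isohb)
lib <- chromophore_library()

records <- simulate_training_set(build_training_grid(),
                                 transport_config(n_photons = 5e4, seed = 1),
                                 lib)
model <- fit_regression(records)
model
#> <hb_model> empirical formulas b, Cth ~ A(420) + A(450) + A(500) + A(585)
#>   alpha (b):   2.83, 1.244, -2.46, 1.862, -0.6233
#>   beta (Cth):  0.01572, -4.696, 8.012, -8.492, 7.417
#>   training R2: b 0.9032, Cth 0.9354 (n = 1250)

# a 64x64 scene: background skin with a vascularized, low-b lesion disk
scene <- lesion_scene(background = skin_parameters(cm = 1, cth = 0.4, b = 3.00),
                      lesion     = skin_parameters(cm = 1, cth = 0.8, b = 2.92),
                      dim = 64, noise_sigma = 0.01, seed = 7)
gen <- generate_image_stack(scene, transport_config(2e4, seed = 8), lib)
maps <- estimate_maps(gen$stack, model)
maps
#> <parameter_maps> 64 x 64 px, 100.0% valid
#>   Cth: median 0.463 vol%  |  b: median 2.988

inside <- scene$class_map == 2
round(c(cth_bg = mean(maps$cth_map[!inside]), cth_lesion = mean(maps$cth_map[inside]),
        b_bg = mean(maps$b_map[!inside]),   b_lesion = mean(maps$b_map[inside])), 3)
#>     cth_bg cth_lesion       b_bg   b_lesion
#>      0.455      0.722      2.990      2.936
```

The lesion shows the expected contrast against the background — strongly
elevated hemoglobin (est. 0.46 → 0.72 vol. % for a true 0.4 → 0.8 step;
the linear formulas compress large excursions, see the methods vignette)
and depressed scattering power — recovered from the images alone. `autoplot(maps)` renders both maps;
`relative_change()` turns a list of weekly maps plus ROI masks into
ΔC<sub>th</sub>% / Δb% time courses.

The interpretation of the two maps: C<sub>th</sub> tracks dermal blood
volume, so a rise flags angiogenesis; b tracks effective scatterer size,
so a fall flags cell swelling and stromal remodeling. Their time courses
over a developing lesion are the package's target readout.

A thin CLI over the same functions lives in `scripts/isohb.R`
(`train`, `estimate`, `timecourse`, `imc`, `simulate` subcommands).

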