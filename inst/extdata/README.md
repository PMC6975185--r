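# Bundled chromophore table

`hb_melanin_extinction_synthetic.csv` — wavelength grid 400–600 nm in 1 nm
steps, columns:

- `wavelength_nm`
- `eps_hbo2`: molar extinction of oxyhemoglobin, cm^-1/M (tetramer
  convention, 64,500 g/mol)
- `eps_hb`: molar extinction of deoxyhemoglobin, cm^-1/M
- `mua_melanosome`: interior-melanosome absorption coefficient, cm^-1

**Provenance: synthetic.** The hemoglobin spectra are a parametric
reconstruction, not a copy of a measured compilation: each spectrum is a
sum of Gaussian bands plus a decaying baseline, anchored at the standard
landmark features of hemoglobin (Soret maxima near 414 nm for HbO2 and
430 nm for Hb at ~5x10^5 cm^-1/M, the HbO2 Q-band doublet at 542/577 nm
and the Hb band at 555 nm at ~5-6x10^4 cm^-1/M, a trough of ~2x10^4
cm^-1/M near 500 nm). Exact isosbestic crossings are imposed at 420, 450,
500 and 585 nm by pulling the deoxy spectrum onto the oxy spectrum within
a ~6 nm Gaussian window around each of those wavelengths. The generating
script is `scratch/make_hb_table.R` in the source repository.

The melanin column is the standard melanosome power law
`mua = 1.70e12 * lambda^-3.48` (cm^-1, lambda in nm).

Values at wavelengths other than the four working bands follow the
synthetic band shapes and should not be quoted against laboratory spectra.
A measured table with the same columns can be swapped in via
`chromophore_library(path = ...)`.
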