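#' Load the bundled chromophore library
#'
#' Returns the wavelength-resolved molar extinction coefficients of oxy- and
#' deoxyhemoglobin together with the melanosome absorption spectrum used to
#' build layer optical properties. The bundled table is a synthetic
#' parametric reconstruction (Gaussian band model anchored at standard
#' landmark features of the hemoglobin spectrum) with exact isosbestic
#' crossings imposed at 420, 450, 500 and 585 nm; see
#' `inst/extdata/README.md` for its construction.
#'
#' @param path Optional path to a CSV with columns `wavelength_nm`,
#'   `eps_hbo2`, `eps_hb` (molar extinction, cm^-1/M, tetramer convention)
#'   and `mua_melanosome` (cm^-1). Defaults to the bundled table
#'   (400-600 nm, 1 nm steps).
#' @param hb_blood_molar Molar concentration of hemoglobin in whole blood
#'   used to convert blood volume fraction to absorption. Default 150 g/L
#'   over 64,500 g/mol (tetramer) = 2.326e-3 M.
#' @return A tibble of class `chromophore_library` with the columns above;
#'   the blood concentration constant is attached as attribute
#'   `hb_blood_molar`.
#' @export
#' @examples
#' lib <- chromophore_library()
#' mua_dermis(0.4, 1, 585, lib)
chromophore_library <- function(path = NULL, hb_blood_molar = 150 / 64500) {
  if (is.null(path)) {
    path <- system.file("extdata", "hb_melanin_extinction_synthetic.csv",
                        package = "isohb", mustWork = TRUE)
  }
  tab <- tibble::as_tibble(read.csv(path))
  need <- c("wavelength_nm", "eps_hbo2", "eps_hb", "mua_melanosome")
  if (!all(need %in% names(tab))) {
    stop("chromophore table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$eps_hbo2 <= 0) || any(tab$eps_hb <= 0)) {
    stop("extinction coefficients must be strictly positive")
  }
  attr(tab, "hb_blood_molar") <- hb_blood_molar
  class(tab) <- c("chromophore_library", class(tab))
  tab
}

lib_lookup <- function(lib, lam, col) {
  idx <- match(lam, lib$wavelength_nm)
  if (anyNA(idx)) {
    stop("wavelength(s) absent from chromophore library: ",
         paste(lam[is.na(idx)], collapse = ", "))
  }
  lib[[col]][idx]
}

#' Reduced scattering coefficient from the power-law model
#'
#' Evaluates `mus' = a * lambda^-b` with the wavelength in nanometres and the
#' result in cm^-1. Under this convention the typical skin amplitude
#' a = 6.3e9 with power b = 3 gives mus'(500 nm) = 50.4 cm^-1.
#'
#' @param a Scattering amplitude (> 0), in units such that the result is in
#'   cm^-1 when `lam` is in nm.
#' @param b Scattering power (dimensionless); larger b means smaller
#'   effective scatterer size.
#' @param lam Wavelength in nm (> 0).
#' @return Reduced scattering coefficient in cm^-1 (vectorised over any
#'   argument).
#' @export
#' @examples
#' reduced_scattering(6.3e9, 3, c(420, 450, 500, 585))
reduced_scattering <- function(a, b, lam) {
  if (any(a <= 0)) stop("scattering amplitude `a` must be positive")
  if (any(lam <= 0)) stop("wavelength must be positive")
  a * lam^(-b)
}

#' Epidermal absorption coefficient from melanin content
#'
#' Linear volume-fraction mixing of the melanosome absorption spectrum:
#' `mua_e = (Cm / 100) * mua_melanosome(lambda)`.
#'
#' @param cm Melanin volume fraction in the epidermis (vol. %, >= 0).
#' @param lam Wavelength in nm (must be present in the library grid).
#' @param lib A [chromophore_library()].
#' @return Absorption coefficient in cm^-1.
#' @export
mua_epidermis <- function(cm, lam, lib) {
  if (any(cm < 0)) stop("melanin concentration must be non-negative")
  (cm / 100) * lib_lookup(lib, lam, "mua_melanosome")
}

#' Dermal absorption coefficient from blood content
#'
#' Converts the blood volume fraction and oxygen saturation to absorption:
#' `mua_d = (Cth / 100) * ln(10) * C_Hb * (so2 * eps_oxy + (1 - so2) * eps_deoxy)`
#' where `C_Hb` is the molar hemoglobin concentration of whole blood
#' attached to the library. At the four isosbestic wavelengths the result is
#' independent of `so2` by construction of the bundled table.
#'
#' @param cth Total hemoglobin (blood) volume fraction in the dermis
#'   (vol. %, >= 0).
#' @param so2 Hemoglobin oxygen saturation, fraction in \[0, 1\].
#' @inheritParams mua_epidermis
#' @return Absorption coefficient in cm^-1.
#' @export
mua_dermis <- function(cth, so2, lam, lib) {
  if (any(cth < 0)) stop("hemoglobin concentration must be non-negative")
  if (any(so2 < 0 | so2 > 1)) stop("so2 must be within [0, 1]")
  eps <- so2 * lib_lookup(lib, lam, "eps_hbo2") +
    (1 - so2) * lib_lookup(lib, lam, "eps_hb")
  (cth / 100) * log(10) * attr(lib, "hb_blood_molar") * eps
}

#' Define one skin tissue state
#'
#' The four unknowns of the model: melanin volume fraction in the epidermis,
#' total hemoglobin volume fraction in the dermis, and the amplitude and
#' power of the reduced-scattering power law (shared by both layers).
#'
#' @param cm Melanin volume fraction, vol. % in (0, 100].
#' @param cth Total hemoglobin volume fraction, vol. % in (0, 100].
#' @param a Scattering amplitude (> 0; cm^-1 when the wavelength is in nm).
#' @param b Scattering power (> 0, dimensionless).
#' @return A one-row tibble of class `skin_parameters`.
#' @export
skin_parameters <- function(cm = 1, cth = 0.4, a = 6.3e9, b = 3.0) {
  stopifnot(length(cm) == 1, length(cth) == 1, length(a) == 1, length(b) == 1)
  if (cm <= 0 || cm > 100) stop("cm must be in (0, 100]")
  if (cth <= 0 || cth > 100) stop("cth must be in (0, 100]")
  if (a <= 0) stop("a must be positive")
  if (b <= 0) stop("b must be positive")
  out <- tibble::tibble(cm = cm, cth = cth, a = a, b = b)
  class(out) <- c("skin_parameters", class(out))
  out
}

#' Build the two-layer skin model consumed by the transport kernel
#'
#' Constructs an epidermis/dermis layer stack at the requested wavelengths.
#' Both layers share the same reduced scattering spectrum (identical-
#' scattering assumption); the epidermis absorbs through melanin and the
#' dermis through hemoglobin. Reduced scattering is converted to `(mus, g)`
#' through the similarity relation `mus = mus' / (1 - g)` with `g = 0.9`
#' unless overridden.
#'
#' @param p A [skin_parameters()] row (or anything with `cm`, `cth`, `a`, `b`).
#' @param d_epi,d_derm Layer thicknesses in mm (defaults 0.06 and 4.94).
#' @param lib A [chromophore_library()].
#' @param lams Wavelengths in nm, default the four isosbestic bands.
#' @param so2 Dermal hemoglobin oxygen saturation (default 1, fully
#'   oxygenated).
#' @param g Scattering anisotropy used in the similarity conversion.
#' @param n Refractive index of both layers (default 1.4 for skin; use 1.33
#'   for aqueous phantoms).
#' @param n_ambient Refractive index above and below the stack.
#' @return A `layer_stack` object: list with `wavelengths`, per-layer
#'   `thickness` (cm), `mua`/`mus` matrices (layer x wavelength), `g`, `n`,
#'   `n_ambient`.
#' @export
build_skin_model <- function(p, d_epi = 0.06, d_derm = 4.94, lib,
                             lams = isosbestic_wavelengths(), so2 = 1,
                             g = 0.9, n = 1.4, n_ambient = 1.0) {
  if (length(lams) == 0) stop("wavelength list must not be empty")
  if (d_epi <= 0 || d_derm <= 0) stop("layer thicknesses must be positive")
  musp <- reduced_scattering(p$a, p$b, lams)
  mus <- musp / (1 - g)
  layer_stack(
    thickness_mm = c(d_epi, d_derm),
    mua = rbind(mua_epidermis(p$cm, lams, lib),
                mua_dermis(p$cth, so2, lams, lib)),
    mus = rbind(mus, mus),
    g = c(g, g), n = c(n, n),
    wavelengths = lams, n_ambient = n_ambient
  )
}

#' Construct a layer stack
#'
#' Low-level constructor for the plane-parallel medium used by
#' [simulate_transport()]. Layers are ordered top first.
#'
#' @param thickness_mm Layer thicknesses in mm.
#' @param mua,mus Matrices (layer x wavelength) of absorption and scattering
#'   coefficients in cm^-1.
#' @param g,n Per-layer anisotropy factors and refractive indices.
#' @param wavelengths Wavelength grid in nm.
#' @param n_ambient Refractive index of the ambient medium (both sides).
#' @return A `layer_stack` object.
#' @export
layer_stack <- function(thickness_mm, mua, mus, g, n, wavelengths,
                        n_ambient = 1.0) {
  mua <- rbind(mua); mus <- rbind(mus)
  nl <- length(thickness_mm)
  if (nl < 1) stop("at least one layer required")
  if (any(thickness_mm <= 0)) stop("thickness must be positive")
  if (nrow(mua) != nl || nrow(mus) != nl) {
    stop("mua/mus must have one row per layer")
  }
  if (ncol(mua) != length(wavelengths) || ncol(mus) != length(wavelengths)) {
    stop("mua/mus must have one column per wavelength")
  }
  if (any(mua < 0) || any(mus < 0)) stop("mua and mus must be non-negative")
  if (any(g <= -1 | g >= 1)) stop("g must be in (-1, 1)")
  if (any(n < 1)) stop("refractive index must be >= 1")
  structure(
    list(thickness_cm = thickness_mm / 10, mua = mua, mus = mus,
         g = g, n = n, wavelengths = wavelengths, n_ambient = n_ambient),
    class = "layer_stack"
  )
}

#' The four isosbestic working wavelengths
#'
#' @return `c(420, 450, 500, 585)` (nm).
#' @export
isosbestic_wavelengths <- function() c(420, 450, 500, 585)

#' @export
print.layer_stack <- function(x, ...) {
  cat("<layer_stack> ", length(x$thickness_cm), " layer(s), ",
      length(x$wavelengths), " wavelength(s): ",
      paste(x$wavelengths, collapse = ", "), " nm\n", sep = "")
  for (i in seq_along(x$thickness_cm)) {
    cat(sprintf("  layer %d: %.3f mm, g = %.2f, n = %.2f, mua = [%s] cm-1\n",
                i, x$thickness_cm[i] * 10, x$g[i], x$n[i],
                paste(signif(x$mua[i, ], 3), collapse = ", ")))
  }
  invisible(x)
}
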