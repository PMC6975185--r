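#' Inverse Monte Carlo recovery of slab optical properties
#'
#' Recovers the absorption coefficient `mua` and reduced scattering
#' coefficient `mus'` of a homogeneous slab from a measured pair of diffuse
#' reflectance and total transmittance. Candidate `(mua, mus')` pairs are
#' evaluated with the forward Monte Carlo kernel (fixed seed, so the
#' objective is deterministic) and updated by coordinate-wise multiplicative
#' steps driven by the signed reflectance/transmittance mismatch; a step is
#' accepted only if it reduces the combined residual `|dR| + |dT|`, and the
#' step size is halved otherwise.
#'
#' @param meas A list or one-row data frame with `wavelength` (nm),
#'   `reflectance`, `transmittance` (fractions), `thickness` (mm), `n`
#'   (refractive index, default 1.33).
#' @param cfg A [transport_config()]; its seed fixes the forward stream used
#'   for every candidate.
#' @param init Optional starting values `c(mua, musp)` in cm^-1.
#' @param threshold Convergence threshold on `|dR| + |dT|` (default 0.005).
#' @param max_iter Maximum accepted or attempted updates.
#' @param g Scattering anisotropy assumed when converting `mus'` to `mus`
#'   (similarity relation).
#' @return A one-row tibble: `mua`, `musp` (cm^-1), `iterations`,
#'   `residual`, `converged`.
#' @export
invert_slab <- function(meas, cfg = transport_config(n_photons = 5e3),
                        init = NULL, threshold = 0.005, max_iter = 200,
                        g = 0.9) {
  Rm <- meas$reflectance; Tm <- meas$transmittance
  if (Rm <= 0 || Tm <= 0) stop("reflectance and transmittance must be positive")
  if (Rm + Tm >= 1) stop("reflectance + transmittance must be < 1")
  n_med <- if (is.null(meas$n)) 1.33 else meas$n
  d_mm <- meas$thickness
  lam <- meas$wavelength

  fwd <- function(mua, musp) {
    st <- layer_stack(thickness_mm = d_mm, mua = matrix(mua),
                      mus = matrix(musp / (1 - g)), g = g, n = n_med,
                      wavelengths = lam, n_ambient = 1.0)
    r <- simulate_transport(st, lam, cfg)
    c(R = r$diffuse_reflectance, T = r$total_transmittance)
  }

  # crude initialization: absorbed fraction drives mua, R/T split drives mus'
  if (is.null(init)) {
    absorbed <- max(1 - Rm - Tm, 0.05)
    init <- c(mua = max(absorbed / (d_mm / 10) * 0.3, 0.05),
              musp = max(Rm / max(Tm, 1e-3) * 10, 1))
  }
  mua <- init[1]; musp <- init[2]
  sim <- fwd(mua, musp)
  best <- abs(Rm - sim["R"]) + abs(Tm - sim["T"])
  step <- 0.5
  iter <- 0L
  while (best > threshold && iter < max_iter && step > 1e-4) {
    iter <- iter + 1L
    dR <- Rm - sim["R"]   # need more scattering if positive
    dT <- Tm - sim["T"]   # need less absorption if positive
    musp_new <- musp * if (dR > 0) (1 + step) else 1 / (1 + step)
    mua_new <- mua * if (dT > 0) 1 / (1 + step) else (1 + step)
    mua_new <- max(mua_new, 1e-6)
    sim_new <- fwd(mua_new, musp_new)
    resid_new <- abs(Rm - sim_new["R"]) + abs(Tm - sim_new["T"])
    if (resid_new < best) {
      mua <- mua_new; musp <- musp_new; sim <- sim_new; best <- resid_new
    } else {
      # try each coordinate alone before shrinking the step
      simA <- fwd(mua_new, musp)
      residA <- abs(Rm - simA["R"]) + abs(Tm - simA["T"])
      simS <- fwd(mua, musp_new)
      residS <- abs(Rm - simS["R"]) + abs(Tm - simS["T"])
      if (min(residA, residS) < best) {
        if (residA <= residS) {
          mua <- mua_new; sim <- simA; best <- residA
        } else {
          musp <- musp_new; sim <- simS; best <- residS
        }
      } else {
        step <- step / 2
      }
    }
  }
  tibble::tibble(mua = unname(mua), musp = unname(musp),
                 iterations = iter, residual = unname(best),
                 converged = best <= threshold)
}

#' Hemoglobin concentration from dermal absorption at 585 nm
#'
#' Inverts the linear blood-absorption relation at 585 nm assuming fully
#' oxygenated blood: `Cth = 100 * mua(585) / (ln(10) * C_Hb * eps(585))`.
#'
#' @param mua585 Absorption coefficient at 585 nm, cm^-1 (>= 0).
#' @param lib A [chromophore_library()].
#' @return Total hemoglobin volume fraction, vol. %.
#' @export
cth_from_mua <- function(mua585, lib) {
  if (any(mua585 < 0)) stop("mua must be non-negative")
  eps <- lib_lookup(lib, 585, "eps_hbo2")
  100 * mua585 / (log(10) * attr(lib, "hb_blood_molar") * eps)
}

#' Scattering power-law parameters from a reduced-scattering spectrum
#'
#' Least-squares fit of `log(mus')` against `log(lambda)`: the slope is
#' `-b` and the intercept `log(a)`.
#'
#' @param musp Named numeric vector of reduced scattering coefficients
#'   (cm^-1), names = wavelengths in nm; or supply `lam` separately.
#' @param lam Wavelengths in nm (defaults to `names(musp)`).
#' @return A one-row tibble with `a` and `b`.
#' @export
#' @examples
#' b_from_musp(reduced_scattering(6.3e9, 3, c(420, 450, 500, 585)),
#'             lam = c(420, 450, 500, 585))
b_from_musp <- function(musp, lam = as.numeric(names(musp))) {
  if (length(musp) < 2) stop("at least 2 wavelengths required for the fit")
  if (any(musp <= 0)) stop("mus' must be positive for a log-log fit")
  fit <- lm(log(musp) ~ log(lam))
  tibble::tibble(a = exp(unname(coef(fit)[1])), b = -unname(coef(fit)[2]))
}
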