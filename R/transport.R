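#' Configure the Monte Carlo transport run
#'
#' @param n_photons Photons launched per wavelength (default 1e5, roughly 1%
#'   relative error on skin reflectance).
#' @param seed Integer seed of the transport random stream; identical seed
#'   and configuration give bit-identical results.
#' @param roulette_threshold Weight below which Russian roulette is played.
#' @param roulette_survival Survival probability of the roulette.
#' @return A `transport_config` list.
#' @export
transport_config <- function(n_photons = 1e5, seed = 1,
                             roulette_threshold = 1e-4,
                             roulette_survival = 0.1) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (roulette_threshold <= 0 || roulette_threshold >= 1) {
    stop("roulette_threshold must be in (0, 1)")
  }
  if (roulette_survival <= 0 || roulette_survival > 1) {
    stop("roulette_survival must be in (0, 1]")
  }
  structure(list(n_photons = as.integer(n_photons), seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival),
            class = "transport_config")
}

# deterministic per-task seed stream derived from a base seed
derive_seed <- function(seed, k) {
  (seed * 48271 + k * 2654435761) %% 2147483647
}

stack_slice <- function(stack, lam) {
  j <- match(lam, stack$wavelengths)
  if (is.na(j)) stop("stack has no optical properties at ", lam, " nm")
  j
}

#' Simulate photon transport at one wavelength
#'
#' Weighted-photon Monte Carlo for a normally incident pencil beam on a
#' plane-parallel layer stack: the specular fraction is deducted at the top
#' interface by Fresnel reflection, free paths are sampled from the
#' Beer-Lambert law on `mua + mus`, scattering follows Henyey-Greenstein,
#' internal reflection at every interface is Fresnel, and low-weight photons
#' are terminated by Russian roulette. All weight leaving the top surface
#' (excluding specular) is tallied as diffuse reflectance; weight leaving
#' the bottom is total transmittance.
#'
#' @param stack A [layer_stack()].
#' @param lam Wavelength in nm (must be on the stack's grid).
#' @param cfg A [transport_config()].
#' @return A one-row tibble: `wavelength`, `specular`, `diffuse_reflectance`,
#'   `total_transmittance`, `absorbed`, `se_reflectance`, `n_photons`,
#'   `rng_seed`. The four energy fractions sum to 1 within 1e-6.
#' @export
#' @examples
#' lib <- chromophore_library()
#' st <- build_skin_model(skin_parameters(), lib = lib)
#' simulate_transport(st, 585, transport_config(n_photons = 2000))
simulate_transport <- function(stack, lam, cfg = transport_config()) {
  j <- stack_slice(stack, lam)
  if (any(stack$mua[, j] + stack$mus[, j] == 0 &
          !is.finite(stack$thickness_cm))) {
    stop("non-interacting layer of infinite thickness cannot terminate")
  }
  res <- cpp_mc_simulate(stack$thickness_cm, stack$mua[, j], stack$mus[, j],
                         stack$g, stack$n, stack$n_ambient, stack$n_ambient,
                         cfg$n_photons, cfg$seed,
                         cfg$roulette_threshold, cfg$roulette_survival)
  tibble::tibble(
    wavelength = lam,
    specular = res$specular,
    diffuse_reflectance = res$diffuse_reflectance,
    total_transmittance = res$total_transmittance,
    absorbed = res$absorbed,
    se_reflectance = res$se_reflectance,
    n_photons = res$n_photons,
    rng_seed = cfg$seed
  )
}

#' Simulate a stack across several wavelengths
#'
#' Runs [simulate_transport()] once per wavelength with a deterministic
#' per-wavelength seed split from `cfg$seed`, so every band has an
#' independent but reproducible photon stream.
#'
#' @inheritParams simulate_transport
#' @param lams Wavelengths in nm.
#' @return A tibble with one row per wavelength (see [simulate_transport()]).
#' @export
simulate_stack_at_wavelengths <- function(stack, lams = stack$wavelengths,
                                          cfg = transport_config()) {
  if (length(lams) == 0) stop("wavelength list must not be empty")
  purrr::map_dfr(seq_along(lams), function(k) {
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(cfg$seed, k)
    simulate_transport(stack, lams[k], cfg_k)
  })
}

# Shared-path forward evaluation: one scattering-only ensemble, absorption
# applied per (mua_epi, mua_derm) combo by Beer-Lambert reweighting.
# mua_combos: matrix with one column per layer. Returns list(Rd, Td, se, specular).
mc_white <- function(stack, lam, cfg, mua_combos) {
  j <- stack_slice(stack, lam)
  res <- cpp_mc_white(stack$thickness_cm, stack$mus[, j], stack$g, stack$n,
                      stack$n_ambient, stack$n_ambient,
                      cfg$n_photons, cfg$seed, rbind(mua_combos))
  list(Rd = res$diffuse_reflectance, Td = res$total_transmittance,
       se = res$se_reflectance, specular = res$specular)
}
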