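#' Define a synthetic imaging scene
#'
#' A scene is a per-pixel map of tissue states drawn from a small set of
#' parameter classes, plus the acquisition imperfections to emulate
#' (multiplicative reflectance noise, optional bit-depth quantization).
#'
#' @param class_map Integer matrix of class ids (1-based).
#' @param classes Tibble with one row per class: columns `cm`, `cth`, `a`,
#'   `b`.
#' @param d_epi,d_derm Layer thicknesses in mm.
#' @param noise_sigma Relative standard deviation of multiplicative Gaussian
#'   reflectance noise (default 0.01, shot-dominated camera regime).
#' @param quantize_bits Optional integer bit depth (e.g. 8) to quantize
#'   pixel values to.
#' @param seed Integer seed recorded in the scene and used for the noise.
#' @return A `scene_phantom` object.
#' @export
scene_phantom <- function(class_map, classes, d_epi = 0.06, d_derm = 4.94,
                          noise_sigma = 0.01, quantize_bits = NULL,
                          seed = 1) {
  if (max(class_map) > nrow(classes) || min(class_map) < 1) {
    stop("class_map refers to undefined classes")
  }
  stopifnot(all(c("cm", "cth", "a", "b") %in% names(classes)))
  structure(list(class_map = class_map, classes = tibble::as_tibble(classes),
                 d_epi = d_epi, d_derm = d_derm, noise_sigma = noise_sigma,
                 quantize_bits = quantize_bits, seed = seed),
            class = "scene_phantom")
}

#' Uniform scene helper
#'
#' @param params A [skin_parameters()] row.
#' @param dim Image side length in pixels.
#' @param ... Passed to [scene_phantom()].
#' @return A `scene_phantom` with a single class everywhere.
#' @export
uniform_scene <- function(params, dim = 64, ...) {
  scene_phantom(matrix(1L, dim, dim), tibble::as_tibble(params), ...)
}

#' Scene with a circular lesion
#'
#' Background tissue with a hard-edged disk of different parameters
#' (e.g. elevated hemoglobin and depressed scattering power, the contrast
#' expected of a vascularized tumor spot).
#'
#' @param background,lesion [skin_parameters()] rows.
#' @param dim Image side length in pixels.
#' @param radius Disk radius in pixels.
#' @param center Disk center (row, col); defaults to the image center.
#' @param ... Passed to [scene_phantom()].
#' @return A `scene_phantom` with class 1 = background, class 2 = lesion.
#' @export
lesion_scene <- function(background, lesion, dim = 64, radius = dim / 6,
                         center = c(dim / 2, dim / 2), ...) {
  cm <- matrix(1L, dim, dim)
  rr <- row(cm) - center[1]; cc <- col(cm) - center[2]
  cm[rr^2 + cc^2 <= radius^2] <- 2L
  scene_phantom(cm, dplyr::bind_rows(tibble::as_tibble(background),
                                     tibble::as_tibble(lesion)), ...)
}

#' Render a scene into a synthetic reflectance stack
#'
#' Forward-simulates the diffuse reflectance of every distinct parameter
#' class at the four wavelengths (one transport run per class and band,
#' cached over identical classes), broadcasts it to the class's pixels,
#' applies multiplicative Gaussian noise and optional quantization, and
#' returns the stack together with ground-truth maps. The white reference is
#' an exact unit field, so the stack normalizes to the noisy reflectance
#' itself. Truth never passes through the estimator.
#'
#' @param scene A [scene_phantom()].
#' @param cfg A [transport_config()].
#' @param lib A [chromophore_library()].
#' @param so2 Blood oxygenation used in the forward simulation.
#' @return A list: `stack` ([reflectance_stack()]), `truth`
#'   (`parameter_maps` holding the generating `cth`/`b` per pixel), and
#'   `class_reflectance` (tibble of noiseless per-class reflectances).
#' @export
generate_image_stack <- function(scene, cfg = transport_config(), lib,
                                 so2 = 1) {
  lams <- isosbestic_wavelengths()
  cls <- scene$classes
  refl <- purrr::map_dfr(seq_len(nrow(cls)), function(i) {
    st <- build_skin_model(cls[i, ], d_epi = scene$d_epi,
                           d_derm = scene$d_derm, lib = lib,
                           lams = lams, so2 = so2)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, i)
    sim <- simulate_stack_at_wavelengths(st, lams, cfg_i)
    if (any(sim$diffuse_reflectance <= 0)) {
      stop("unreachable optical properties for scene class ", i)
    }
    dplyr::mutate(sim, class = i)
  })
  dims <- dim(scene$class_map)
  set.seed(scene$seed)
  images <- list(); white <- list()
  for (k in seq_along(lams)) {
    base <- matrix(0, dims[1], dims[2])
    for (i in seq_len(nrow(cls))) {
      r <- refl$diffuse_reflectance[refl$class == i & refl$wavelength == lams[k]]
      base[scene$class_map == i] <- r
    }
    if (scene$noise_sigma > 0) {
      base <- base * (1 + scene$noise_sigma * matrix(stats::rnorm(prod(dims)),
                                                     dims[1], dims[2]))
    }
    if (!is.null(scene$quantize_bits)) {
      levels <- 2^scene$quantize_bits - 1
      base <- round(base * levels) / levels
    }
    images[[as.character(lams[k])]] <- base
    white[[as.character(lams[k])]] <- 1
  }
  truth <- structure(list(
    cth_map = matrix(cls$cth[scene$class_map], dims[1], dims[2]),
    b_map = matrix(cls$b[scene$class_map], dims[1], dims[2]),
    valid_mask = matrix(TRUE, dims[1], dims[2]), dims = dims,
    timestamp = NA_character_
  ), class = "parameter_maps")
  list(stack = reflectance_stack(images, white),
       truth = truth, class_reflectance = refl)
}

#' Generate an in-silico phantom validation set
#'
#' Emulates a bench validation set of two-layer phantoms with different
#' `(Cth, b)` combinations: parameters are drawn on a maximin
#' latin-hypercube design over the requested ranges, each phantom's four-band diffuse
#' reflectance is forward-simulated through the same two-layer geometry the
#' regression model is trained on, multiplicative reflectance noise is
#' added, and a 1 mm single-slab reflectance/transmittance pair (aqueous
#' refractive index) is simulated per band for inverse Monte Carlo use.
#'
#' @param n Number of phantoms (default 12).
#' @param ranges Named list of `c(min, max)` intervals for `cm`, `cth`,
#'   `a`, `b`. Defaults sit in the interior of the default training grid
#'   with the melanin analogue fixed: `cm = 1`, `cth` 0.3-0.9 vol. %,
#'   `a` 5.8e9-6.8e9, `b` 2.92-3.08.
#' @param cfg A [transport_config()].
#' @param lib A [chromophore_library()].
#' @param seed Seed for the design and the noise.
#' @param noise_sigma Relative reflectance noise (default 0.01).
#' @param slab_thickness_mm,slab_n Slab geometry for the (R, T)
#'   measurements (defaults 1.0 mm, n = 1.33).
#' @param slab Whether to simulate the slab (R, T) pairs (default TRUE).
#' @return A list of tibbles: `truth` (phantom, cm, cth, a, b),
#'   `reflectance` (phantom, wavelength, R noiseless, R_noisy), and `slab`
#'   (phantom, wavelength, mua, musp, reflectance, transmittance,
#'   thickness, n) or NULL.
#' @export
generate_phantom_set <- function(n = 12,
                                 ranges = list(cm = c(1, 1),
                                               cth = c(0.3, 0.9),
                                               a = c(5.8e9, 6.8e9),
                                               b = c(2.92, 3.08)),
                                 cfg = transport_config(), lib,
                                 seed = 1, noise_sigma = 0.01,
                                 slab_thickness_mm = 1.0, slab_n = 1.33,
                                 slab = TRUE) {
  if (n < 2) stop("at least 2 phantoms required")
  grid_lims <- list(cth = c(0.2, 1.0), b = c(2.90, 3.10))
  for (nm in names(grid_lims)) {
    if (ranges[[nm]][1] < grid_lims[[nm]][1] ||
        ranges[[nm]][2] > grid_lims[[nm]][2]) {
      warning("range for ", nm, " extends beyond the default training grid; ",
              "estimates will extrapolate")
    }
  }
  set.seed(seed)
  u <- lhs::maximinLHS(n, 4)
  span <- function(u, r) r[1] + u * (r[2] - r[1])
  truth <- tibble::tibble(
    phantom = seq_len(n),
    cm = span(u[, 1], ranges$cm),
    cth = span(u[, 2], ranges$cth),
    a = span(u[, 3], ranges$a),
    b = span(u[, 4], ranges$b)
  )
  lams <- isosbestic_wavelengths()
  refl <- purrr::map_dfr(seq_len(n), function(i) {
    st <- build_skin_model(truth[i, ], lib = lib, lams = lams)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, 1000 + i)
    sim <- simulate_stack_at_wavelengths(st, lams, cfg_i)
    tibble::tibble(phantom = i, wavelength = lams,
                   reflectance = sim$diffuse_reflectance)
  })
  refl$reflectance_noisy <- refl$reflectance *
    (1 + noise_sigma * stats::rnorm(nrow(refl)))
  slab_tbl <- NULL
  if (slab) {
    slab_tbl <- purrr::map_dfr(seq_len(n), function(i) {
      musp <- reduced_scattering(truth$a[i], truth$b[i], lams)
      mua <- mua_dermis(truth$cth[i], 1, lams, lib)
      st <- layer_stack(thickness_mm = slab_thickness_mm,
                        mua = matrix(mua, 1), mus = matrix(musp / 0.1, 1),
                        g = 0.9, n = slab_n, wavelengths = lams)
      cfg_i <- cfg
      cfg_i$seed <- derive_seed(cfg$seed, 2000 + i)
      sim <- simulate_stack_at_wavelengths(st, lams, cfg_i)
      tibble::tibble(phantom = i, wavelength = lams, mua = mua, musp = musp,
                     reflectance = sim$diffuse_reflectance,
                     transmittance = sim$total_transmittance,
                     thickness = slab_thickness_mm, n = slab_n)
    })
  }
  list(truth = truth, reflectance = refl, slab = slab_tbl)
}

#' Estimate Cth and b for a phantom reflectance table
#'
#' Convenience wrapper: converts the (noisy) four-band reflectances of
#' [generate_phantom_set()] to absorbance and applies the fitted model.
#'
#' @param phantoms Output of [generate_phantom_set()].
#' @param model An `hb_model`.
#' @param noisy Use the noisy reflectances (default TRUE).
#' @return The `truth` tibble with `cth_est` and `b_est` columns appended.
#' @export
estimate_phantoms <- function(phantoms, model, noisy = TRUE) {
  col <- if (noisy) "reflectance_noisy" else "reflectance"
  wide <- tidyr::pivot_wider(
    dplyr::mutate(phantoms$reflectance,
                  A = absorbance(.data[[col]]),
                  band = paste0("A", .data$wavelength)),
    id_cols = "phantom", names_from = "band", values_from = "A"
  )
  est <- predict(model, wide)
  dplyr::bind_cols(phantoms$truth, est)
}

#' Synthetic multi-week time course
#'
#' Renders one stack per scheduled week, scaling the baseline scene's
#' hemoglobin and scattering-power values by the scheduled multipliers
#' (the in-silico analogue of weekly acquisitions over a developing
#' lesion).
#'
#' @param base_scene A [scene_phantom()]; its parameters are week-0 truth.
#' @param schedule Tibble with columns `week`, `cth_mult`, `b_mult`; must
#'   contain week 0 with multipliers (1, 1).
#' @param cfg,lib,so2 As in [generate_image_stack()].
#' @return A list with `weeks` (vector), `stacks` (list of
#'   [reflectance_stack()]), `truths` (list of `parameter_maps`), and
#'   `schedule`.
#' @export
generate_timecourse <- function(base_scene, schedule,
                                cfg = transport_config(), lib, so2 = 1) {
  stopifnot(all(c("week", "cth_mult", "b_mult") %in% names(schedule)))
  i0 <- which(schedule$week == 0)
  if (length(i0) != 1 || schedule$cth_mult[i0] != 1 || schedule$b_mult[i0] != 1) {
    stop("schedule must contain week 0 with multipliers (1, 1)")
  }
  out <- purrr::map(seq_len(nrow(schedule)), function(i) {
    sc <- base_scene
    sc$classes$cth <- sc$classes$cth * schedule$cth_mult[i]
    sc$classes$b <- sc$classes$b * schedule$b_mult[i]
    sc$seed <- derive_seed(base_scene$seed, i)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, 10 * i)
    generate_image_stack(sc, cfg_i, lib, so2 = so2)
  })
  list(weeks = schedule$week,
       stacks = purrr::map(out, "stack"),
       truths = purrr::map(out, "truth"),
       schedule = schedule)
}

#' Layer-thickness sensitivity of the estimates
#'
#' The regression model is trained at fixed layer thicknesses (0.06 mm
#' epidermis, 4.94 mm dermis). This study forward-simulates a fixed tissue
#' state at perturbed thicknesses (varying one layer at a time), estimates
#' `(Cth, b)` with the fixed model, and reports the relative errors against
#' the generating values.
#'
#' @param model An `hb_model` trained at the default thicknesses.
#' @param cfg A [transport_config()].
#' @param lib A [chromophore_library()].
#' @param epi_thicknesses Epidermis test thicknesses in mm
#'   (default 0.005, 0.01, 0.03, 0.06).
#' @param derm_thicknesses Dermis test thicknesses in mm
#'   (default 3.5, 4, 4.5, 4.94).
#' @param params Fixed tissue state (default Cm 1 vol. %, Cth 0.4 vol. %,
#'   a 6.3e9, b 3.00).
#' @return A tibble: `varied` (`"epidermis"` or `"dermis"`),
#'   `thickness_mm`, `cth_est`, `b_est`, `rel_err_cth`, `rel_err_b`
#'   (fractions).
#' @export
thickness_sensitivity <- function(model, cfg = transport_config(), lib,
                                  epi_thicknesses = c(0.005, 0.01, 0.03, 0.06),
                                  derm_thicknesses = c(3.5, 4, 4.5, 4.94),
                                  params = skin_parameters(cm = 1, cth = 0.4,
                                                           a = 6.3e9, b = 3.0)) {
  lams <- isosbestic_wavelengths()
  run_case <- function(varied, d_epi, d_derm, k) {
    st <- build_skin_model(params, d_epi = d_epi, d_derm = d_derm,
                           lib = lib, lams = lams)
    cfg_k <- cfg
    cfg_k$seed <- derive_seed(cfg$seed, k)
    sim <- simulate_stack_at_wavelengths(st, lams, cfg_k)
    A <- as.list(setNames(-log10(sim$diffuse_reflectance),
                          paste0("A", sim$wavelength)))
    est <- predict(model, A)
    tibble::tibble(
      varied = varied,
      thickness_mm = if (varied == "epidermis") d_epi else d_derm,
      cth_est = est$cth_est, b_est = est$b_est,
      rel_err_cth = (est$cth_est - params$cth) / params$cth,
      rel_err_b = (est$b_est - params$b) / params$b
    )
  }
  dplyr::bind_rows(
    purrr::map_dfr(seq_along(epi_thicknesses), function(i) {
      run_case("epidermis", epi_thicknesses[i], 4.94, i)
    }),
    purrr::map_dfr(seq_along(derm_thicknesses), function(i) {
      run_case("dermis", 0.06, derm_thicknesses[i], 100 + i)
    })
  )
}
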