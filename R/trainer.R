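#' Build the training grid of tissue states
#'
#' Full Cartesian product of the scattering amplitude, scattering power,
#' melanin and hemoglobin concentration lists, in a fixed deterministic
#' order (`a` outermost, then `b`, then `cm`, with `cth` varying fastest).
#' The defaults reproduce the canonical design: 5 x 5 x 10 x 5 = 1250
#' states built from 25 distinct scattering spectra.
#'
#' @param a_values Scattering amplitudes (default 5.3e9 to 7.3e9, step 5e8).
#' @param b_values Scattering powers (default 2.90 to 3.10, step 0.05).
#' @param cm_values Melanin vol. % (default 1 to 10, step 1).
#' @param cth_values Hemoglobin vol. % (default 0.2 to 1.0, step 0.2).
#' @return A tibble of class `training_grid` with columns `a`, `b`, `cm`,
#'   `cth`.
#' @export
#' @examples
#' nrow(build_training_grid())  # 1250
build_training_grid <- function(a_values = seq(5.3e9, 7.3e9, by = 0.5e9),
                                b_values = seq(2.90, 3.10, by = 0.05),
                                cm_values = seq(1, 10, by = 1),
                                cth_values = seq(0.2, 1.0, by = 0.2)) {
  vals <- list(a = a_values, b = b_values, cm = cm_values, cth = cth_values)
  for (nm in names(vals)) {
    if (length(vals[[nm]]) == 0) stop("empty value list for ", nm)
    if (anyDuplicated(vals[[nm]])) stop("duplicate values in ", nm, " list")
  }
  grid <- tidyr::expand_grid(a = a_values, b = b_values,
                             cm = cm_values, cth = cth_values)
  class(grid) <- c("training_grid", class(grid))
  grid
}

#' Simulate the four-band absorbances of every grid state
#'
#' Forward-simulates the diffuse reflectance of each tissue state at the
#' four isosbestic wavelengths and converts it to absorbance
#' `A = -log10(R)`. States sharing a scattering spectrum `(a, b)` reuse one
#' scattering-only photon-path ensemble per wavelength, with absorption
#' applied by Beer-Lambert reweighting of the recorded per-layer path
#' lengths (method `"shared-paths"`, the default); `method = "direct"` runs
#' an independent weighted simulation per state. Both estimators are
#' unbiased for the same reflectance.
#'
#' @param grid A [build_training_grid()] tibble.
#' @param cfg A [transport_config()]; `cfg$n_photons` photons are used per
#'   scattering spectrum and wavelength.
#' @param lib A [chromophore_library()].
#' @param d_epi,d_derm Layer thicknesses in mm.
#' @param so2 Blood oxygen saturation used in the simulation (default 1).
#' @param method `"shared-paths"` or `"direct"` (see above).
#' @return A tibble with the grid columns plus `A420`, `A450`, `A500`,
#'   `A585` and `R420` ... `R585`; attributes `grid_hash` (provenance of
#'   grid + transport configuration + library) and `config`. States with a
#'   simulated reflectance of 0 in any band are dropped with a warning.
#' @export
simulate_training_set <- function(grid, cfg = transport_config(), lib,
                                  d_epi = 0.06, d_derm = 4.94, so2 = 1,
                                  method = c("shared-paths", "direct")) {
  method <- match.arg(method)
  lams <- isosbestic_wavelengths()
  scatter_groups <- dplyr::group_split(dplyr::group_by(grid, .data$a, .data$b))

  records <- purrr::map_dfr(seq_along(scatter_groups), function(gi) {
    sub <- scatter_groups[[gi]]
    st <- build_skin_model(list(cm = 1, cth = 0.4, a = sub$a[1], b = sub$b[1]),
                           d_epi = d_epi, d_derm = d_derm, lib = lib,
                           lams = lams, so2 = so2)
    R <- matrix(NA_real_, nrow(sub), length(lams))
    for (k in seq_along(lams)) {
      combos <- cbind(mua_epidermis(sub$cm, rep(lams[k], nrow(sub)), lib),
                      mua_dermis(sub$cth, so2, rep(lams[k], nrow(sub)), lib))
      cfg_k <- cfg
      cfg_k$seed <- derive_seed(cfg$seed, gi * 101 + k)
      if (method == "shared-paths") {
        R[, k] <- mc_white(st, lams[k], cfg_k, combos)$Rd
      } else {
        R[, k] <- vapply(seq_len(nrow(sub)), function(i) {
          sti <- st
          sti$mua <- rbind(rep(combos[i, 1], length(lams)),
                           rep(combos[i, 2], length(lams)))
          cfg_i <- cfg_k
          cfg_i$seed <- derive_seed(cfg_k$seed, i)
          simulate_transport(sti, lams[k], cfg_i)$diffuse_reflectance
        }, numeric(1))
      }
    }
    colnames(R) <- paste0("R", lams)
    dplyr::bind_cols(sub, tibble::as_tibble(R))
  })

  bad <- records$R420 <= 0 | records$R450 <= 0 |
    records$R500 <= 0 | records$R585 <= 0
  if (any(bad)) {
    warning(sum(bad), " state(s) with zero simulated reflectance excluded")
    records <- records[!bad, , drop = FALSE]
  }
  for (k in isosbestic_wavelengths()) {
    records[[paste0("A", k)]] <- -log10(records[[paste0("R", k)]])
  }
  attr(records, "config") <- list(
    n_photons = cfg$n_photons, seed = cfg$seed, d_epi = d_epi,
    d_derm = d_derm, so2 = so2, method = method
  )
  attr(records, "grid_hash") <- rlang::hash(list(
    grid = as.data.frame(grid), cfg = unclass(cfg),
    d_epi = d_epi, d_derm = d_derm, so2 = so2,
    lib = as.data.frame(lib), hb = attr(lib, "hb_blood_molar")
  ))
  records
}

#' Fit the empirical regression formulas for b and Cth
#'
#' Ordinary least squares of the scattering power and of the hemoglobin
#' concentration on the four absorbances:
#' `b = alpha0 + alpha1 A(420) + alpha2 A(450) + alpha3 A(500) + alpha4 A(585)`
#' and likewise `Cth = beta0 + ... + beta4 A(585)`.
#'
#' @param records Output of [simulate_training_set()] (needs columns `b`,
#'   `cth`, `A420`, `A450`, `A500`, `A585`).
#' @return An object of class `hb_model`: coefficient vectors `alpha` (for
#'   b) and `beta` (for Cth), training R-squared for both fits, the number
#'   of records, and the `grid_hash` provenance carried over from the
#'   records.
#' @export
fit_regression <- function(records) {
  need <- c("b", "cth", "A420", "A450", "A500", "A585")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (nrow(records) < 6) stop("at least 6 records required to fit 5 coefficients")
  X <- cbind(1, records$A420, records$A450, records$A500, records$A585)
  qrX <- qr(X)
  if (qrX$rank < 5) {
    cols <- c("(intercept)", "A420", "A450", "A500", "A585")
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("collinear absorbance design; dependent column(s): ",
         paste(cols[setdiff(seq_len(5), keep)], collapse = ", "))
  }
  fit_b <- lm(b ~ A420 + A450 + A500 + A585, data = records)
  fit_c <- lm(cth ~ A420 + A450 + A500 + A585, data = records)
  r2 <- function(fit, y) {
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  }
  structure(list(
    alpha = setNames(coef(fit_b), c("a0", "a1", "a2", "a3", "a4")),
    beta = setNames(coef(fit_c), c("b0", "b1", "b2", "b3", "b4")),
    training_r2_b = r2(fit_b, records$b),
    training_r2_cth = r2(fit_c, records$cth),
    n_records = nrow(records),
    grid_hash = attr(records, "grid_hash"),
    created = format(Sys.time(), tz = "UTC")
  ), class = "hb_model")
}

#' Apply the fitted formulas to absorbance quadruples
#'
#' @param object An `hb_model`.
#' @param newdata Data frame (or named list of equal-length vectors) with
#'   columns `A420`, `A450`, `A500`, `A585`.
#' @param ... Unused.
#' @return A tibble with columns `b_est` and `cth_est`.
#' @export
predict.hb_model <- function(object, newdata, ...) {
  X <- cbind(1, newdata$A420, newdata$A450, newdata$A500, newdata$A585)
  tibble::tibble(b_est = drop(X %*% object$alpha),
                 cth_est = drop(X %*% object$beta))
}

#' @export
print.hb_model <- function(x, ...) {
  cat("<hb_model> empirical formulas b, Cth ~ A(420) + A(450) + A(500) + A(585)\n")
  cat("  alpha (b):  ", paste(signif(x$alpha, 4), collapse = ", "), "\n")
  cat("  beta (Cth): ", paste(signif(x$beta, 4), collapse = ", "), "\n")
  cat(sprintf("  training R2: b %.4f, Cth %.4f (n = %d)\n",
              x$training_r2_b, x$training_r2_cth, x$n_records))
  invisible(x)
}

#' Tidy the fitted regression coefficients
#'
#' @param x An `hb_model`.
#' @param ... Unused.
#' @return A tibble with one row per (response, term): columns `response`
#'   (`"b"` or `"cth"`), `term`, `estimate`.
#' @export
tidy.hb_model <- function(x, ...) {
  terms <- c("(Intercept)", "A420", "A450", "A500", "A585")
  dplyr::bind_rows(
    tibble::tibble(response = "b", term = terms, estimate = unname(x$alpha)),
    tibble::tibble(response = "cth", term = terms, estimate = unname(x$beta))
  )
}

#' One-row model summary
#'
#' @param x An `hb_model`.
#' @param ... Unused.
#' @return A tibble: `r2_b`, `r2_cth`, `n_records`, `grid_hash`.
#' @export
glance.hb_model <- function(x, ...) {
  tibble::tibble(r2_b = x$training_r2_b, r2_cth = x$training_r2_cth,
                 n_records = x$n_records, grid_hash = x$grid_hash)
}

#' @rdname tidy.hb_model
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname glance.hb_model
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Serialize / restore a fitted model as JSON
#'
#' @param model An `hb_model`.
#' @param path File path.
#' @return `write_hb_model` returns `path` invisibly; `read_hb_model`
#'   returns the restored `hb_model`.
#' @export
write_hb_model <- function(model, path) {
  jsonlite::write_json(
    list(alpha = unname(model$alpha), beta = unname(model$beta),
         r2 = list(b = model$training_r2_b, cth = model$training_r2_cth),
         n_records = model$n_records, grid_hash = model$grid_hash,
         created = model$created),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_hb_model
#' @export
read_hb_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    alpha = setNames(x$alpha, c("a0", "a1", "a2", "a3", "a4")),
    beta = setNames(x$beta, c("b0", "b1", "b2", "b3", "b4")),
    training_r2_b = x$r2$b, training_r2_cth = x$r2$cth,
    n_records = x$n_records, grid_hash = x$grid_hash, created = x$created
  ), class = "hb_model")
}
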