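#' Assemble a multispectral reflectance stack
#'
#' Bundles the four per-wavelength sample images `Is` with their white
#' reference `Iw` (full image or one scalar per band). The white reference
#' is a measurement of a standard diffuser used to normalize out the source
#' spectrum and optics.
#'
#' @param images Named list of numeric matrices, names `"420"`, `"450"`,
#'   `"500"`, `"585"` (any order; reordered internally). All must share
#'   dimensions.
#' @param white Named list matching `images`: matrices of the same size or
#'   scalars.
#' @param timestamp Optional acquisition label.
#' @return A `reflectance_stack` object.
#' @export
reflectance_stack <- function(images, white, timestamp = NA_character_) {
  lams <- as.character(isosbestic_wavelengths())
  if (!setequal(names(images), lams)) {
    stop("images must be named exactly ", paste(lams, collapse = ", "))
  }
  if (!setequal(names(white), lams)) {
    stop("white reference must be named exactly ", paste(lams, collapse = ", "))
  }
  images <- images[lams]
  white <- white[lams]
  dims <- dim(images[[1]])
  for (nm in lams) {
    if (!identical(dim(images[[nm]]), dims)) {
      stop("all bands must share pixel dimensions")
    }
    if (length(white[[nm]]) == 1) {
      white[[nm]] <- matrix(white[[nm]], dims[1], dims[2])
    }
    if (!identical(dim(white[[nm]]), dims)) {
      stop("white reference dimensions must match the sample images")
    }
  }
  structure(list(images = images, white = white,
                 wavelengths = isosbestic_wavelengths(),
                 dims = dims, timestamp = timestamp),
            class = "reflectance_stack")
}

#' Normalize a stack to diffuse reflectance
#'
#' Computes `R = Is / Iw` per band and pixel. Pixels where the white
#' reference is zero, or where the ratio is non-positive or exceeds 1, are
#' flagged invalid rather than propagated.
#'
#' @param stack A [reflectance_stack()].
#' @return A list with `R` (named list of reflectance matrices) and `valid`
#'   (logical matrix, TRUE where every band is usable).
#' @export
normalize_reflectance <- function(stack) {
  lams <- as.character(stack$wavelengths)
  valid <- matrix(TRUE, stack$dims[1], stack$dims[2])
  R <- list()
  for (nm in lams) {
    Iw <- stack$white[[nm]]
    r <- ifelse(Iw == 0, NA_real_, stack$images[[nm]] / Iw)
    ok <- !is.na(r) & r > 0 & r <= 1
    valid <- valid & ok
    r[!ok] <- NA_real_
    R[[nm]] <- r
  }
  list(R = R, valid = valid)
}

#' Absorbance of a reflectance image
#'
#' `A = -log10(R)`; `A(1) = 0` and each factor-of-10 drop in reflectance
#' adds one absorbance unit.
#'
#' @param R Numeric vector/matrix of reflectance values; `NA` passes
#'   through.
#' @return Absorbance of the same shape.
#' @export
#' @examples
#' absorbance(c(1, 0.1, 0.01))  # 0 1 2
absorbance <- function(R) {
  if (any(R <= 0, na.rm = TRUE)) {
    stop("absorbance undefined for non-positive reflectance")
  }
  -log10(R)
}

#' Per-pixel estimation of Cth and b maps
#'
#' Normalizes the stack, converts each band to absorbance, and applies the
#' fitted linear formulas pixelwise. No transport simulation is involved;
#' runtime is linear in the pixel count. Estimates falling outside the
#' plausible ranges (negative Cth, b outside \[1, 4\]) are retained in the
#' maps but flagged in `valid_mask`.
#'
#' @param stack A [reflectance_stack()].
#' @param model An `hb_model` from [fit_regression()].
#' @param expected_hash Optional grid hash the stack's acquisition declares;
#'   if supplied and different from `model$grid_hash`, estimation refuses.
#' @return A `parameter_maps` object: matrices `cth_map` (vol. %), `b_map`,
#'   and `valid_mask`.
#' @export
estimate_maps <- function(stack, model, expected_hash = NULL) {
  if (!inherits(model, "hb_model")) stop("model must be an hb_model")
  if (!is.null(expected_hash) && !identical(expected_hash, model$grid_hash)) {
    stop("model grid_hash does not match the hash declared for this stack")
  }
  nr <- normalize_reflectance(stack)
  A <- lapply(nr$R, function(r) -log10(r))
  b_map <- model$alpha[1] + model$alpha[2] * A[["420"]] +
    model$alpha[3] * A[["450"]] + model$alpha[4] * A[["500"]] +
    model$alpha[5] * A[["585"]]
  cth_map <- model$beta[1] + model$beta[2] * A[["420"]] +
    model$beta[3] * A[["450"]] + model$beta[4] * A[["500"]] +
    model$beta[5] * A[["585"]]
  in_range <- !is.na(b_map) & !is.na(cth_map) &
    cth_map >= 0 & b_map >= 1 & b_map <= 4
  valid <- nr$valid & in_range
  structure(list(cth_map = cth_map, b_map = b_map, valid_mask = valid,
                 dims = stack$dims, timestamp = stack$timestamp),
            class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  cat(sprintf("<parameter_maps> %d x %d px, %.1f%% valid\n",
              x$dims[1], x$dims[2], 100 * mean(x$valid_mask)))
  cat(sprintf("  Cth: median %.3f vol%%  |  b: median %.3f\n",
              stats::median(x$cth_map[x$valid_mask]),
              stats::median(x$b_map[x$valid_mask])))
  invisible(x)
}

#' Flatten parameter maps to a tibble
#'
#' @param x A `parameter_maps` object.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `cth`, `b`, `valid`.
#' @export
as_tibble.parameter_maps <- function(x, ...) {
  tibble::tibble(
    row = rep(seq_len(x$dims[1]), times = x$dims[2]),
    col = rep(seq_len(x$dims[2]), each = x$dims[1]),
    cth = as.vector(x$cth_map),
    b = as.vector(x$b_map),
    valid = as.vector(x$valid_mask)
  )
}

#' Relative-change time course over regions of interest
#'
#' For every ROI, averages the Cth and b maps spatially at each time point
#' and expresses the change from baseline as
#' `dCth% = (Cth - Cth_c) / Cth_c * 100` and `db% = (b - b_c) / b_c * 100`,
#' where the baseline values `Cth_c`, `b_c` are the ROI means at
#' `baseline_index`.
#'
#' @param maps_list List of `parameter_maps`, one per time point.
#' @param rois Named list of logical matrices (TRUE inside the ROI), same
#'   dimensions as the maps.
#' @param times Numeric labels (e.g. week indices), one per map; defaults
#'   to `0, 1, ...`.
#' @param baseline_index Position of the baseline acquisition in
#'   `maps_list` (default 1).
#' @return A tibble: `time`, `roi`, `mean_cth`, `mean_b`, `delta_cth_pct`,
#'   `delta_b_pct`. Baseline rows have both deltas exactly 0.
#' @export
relative_change <- function(maps_list, rois,
                            times = seq_along(maps_list) - 1,
                            baseline_index = 1) {
  stopifnot(length(times) == length(maps_list))
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  roi_mean <- function(maps, mask) {
    use <- mask & maps$valid_mask
    if (!any(use)) stop("ROI has no valid pixels at one time point")
    c(cth = mean(maps$cth_map[use]), b = mean(maps$b_map[use]))
  }
  out <- purrr::map_dfr(seq_along(maps_list), function(i) {
    purrr::map_dfr(names(rois), function(rn) {
      m <- roi_mean(maps_list[[i]], rois[[rn]])
      tibble::tibble(time = times[i], roi = rn,
                     mean_cth = unname(m["cth"]), mean_b = unname(m["b"]))
    })
  })
  base <- out[out$time == times[baseline_index], c("roi", "mean_cth", "mean_b")]
  names(base) <- c("roi", "cth_c", "b_c")
  if (any(base$cth_c == 0) || any(base$b_c == 0)) {
    stop("baseline ROI mean of 0: relative change undefined")
  }
  out <- dplyr::left_join(out, base, by = "roi")
  out$delta_cth_pct <- (out$mean_cth - out$cth_c) / out$cth_c * 100
  out$delta_b_pct <- (out$mean_b - out$b_c) / out$b_c * 100
  out$delta_cth_pct[out$time == times[baseline_index]] <- 0
  out$delta_b_pct[out$time == times[baseline_index]] <- 0
  dplyr::select(out, -"cth_c", -"b_c")
}
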