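#' Write a reflectance stack to disk
#'
#' One 32-bit float grayscale TIFF per band plus the white reference, with a
#' YAML sidecar naming the wavelengths and files.
#'
#' @param stack A [reflectance_stack()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The sidecar path, invisibly.
#' @export
write_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lams <- as.character(stack$wavelengths)
  bands <- list()
  for (nm in lams) {
    fs <- paste0(prefix, "_", nm, "nm.tif")
    fw <- paste0(prefix, "_", nm, "nm_white.tif")
    tiff::writeTIFF(clamp01(stack$images[[nm]]), file.path(dir, fs),
                    bits.per.sample = 32)
    tiff::writeTIFF(clamp01(stack$white[[nm]]), file.path(dir, fw),
                    bits.per.sample = 32)
    bands[[nm]] <- list(wavelength_nm = as.numeric(nm), sample = fs, white = fw)
  }
  sidecar <- file.path(dir, paste0(prefix, ".yaml"))
  yaml::write_yaml(list(bands = bands, timestamp = stack$timestamp), sidecar)
  invisible(sidecar)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Read a reflectance stack written by [write_stack()]
#'
#' @param sidecar Path to the YAML sidecar.
#' @return A [reflectance_stack()].
#' @export
read_stack <- function(sidecar) {
  meta <- yaml::read_yaml(sidecar)
  dir <- dirname(sidecar)
  images <- list(); white <- list()
  for (nm in names(meta$bands)) {
    images[[nm]] <- as_matrix_gray(tiff::readTIFF(
      file.path(dir, meta$bands[[nm]]$sample)))
    white[[nm]] <- as_matrix_gray(tiff::readTIFF(
      file.path(dir, meta$bands[[nm]]$white)))
  }
  ts <- meta$timestamp
  reflectance_stack(images, white,
                    timestamp = if (is.null(ts)) NA_character_ else ts)
}

as_matrix_gray <- function(x) {
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

#' Write parameter maps as float TIFFs
#'
#' Cth is scaled by 1/100 into the unit range expected by the TIFF writer
#' (vol. fraction instead of vol. %); b is scaled by 1/10.
#'
#' @param maps A `parameter_maps` object.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_maps <- function(maps, dir, prefix = "maps") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("_cth.tif", "_b.tif", "_valid.tif")))
  tiff::writeTIFF(clamp01(maps$cth_map / 100), paths[1], bits.per.sample = 32)
  tiff::writeTIFF(clamp01(maps$b_map / 10), paths[2], bits.per.sample = 32)
  tiff::writeTIFF(maps$valid_mask * 1, paths[3], bits.per.sample = 32)
  invisible(paths)
}

#' Read parameter maps written by [write_maps()]
#'
#' Undoes the unit-range scaling applied on write (Cth x100, b x10).
#'
#' @param dir Directory holding the map TIFFs.
#' @param prefix File-name prefix used on write.
#' @return A `parameter_maps` object.
#' @export
read_maps <- function(dir, prefix = "maps") {
  cth <- as_matrix_gray(tiff::readTIFF(
    file.path(dir, paste0(prefix, "_cth.tif")))) * 100
  b <- as_matrix_gray(tiff::readTIFF(
    file.path(dir, paste0(prefix, "_b.tif")))) * 10
  valid <- as_matrix_gray(tiff::readTIFF(
    file.path(dir, paste0(prefix, "_valid.tif")))) > 0.5
  structure(list(cth_map = cth, b_map = b, valid_mask = valid,
                 dims = dim(cth), timestamp = NA_character_),
            class = "parameter_maps")
}

#' Write a time course as CSV
#'
#' @param tc Output of [relative_change()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  write.csv(tc, path, row.names = FALSE)
  invisible(path)
}
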