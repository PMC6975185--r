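#!/usr/bin/env Rscript
# Thin command-line front end over the isohb package.
#
#   Rscript scripts/isohb.R train --photons N --seed S --out model.json
#   Rscript scripts/isohb.R estimate --model model.json --stack stack.yaml --out maps/
#   Rscript scripts/isohb.R timecourse --maps-dir maps/ --rois rois/
#                                      [--baseline 1] --out tc.csv
#   Rscript scripts/isohb.R imc --measurements phantoms.csv --out props.csv
#                               [--threshold 0.005] [--photons N] [--seed S]
#   Rscript scripts/isohb.R simulate --dim 64 --photons N --seed S --out scene_dir/
#
# `estimate` expects the TIFF + YAML sidecar layout written by
# isohb::write_stack(); `imc` expects a CSV with columns
# phantom, wavelength, reflectance, transmittance, thickness, n.

suppressPackageStartupMessages(library(isohb))

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: isohb.R <train|estimate|imc|simulate> ...")
cmd <- argv[1]
args <- argv[-1]
get_arg <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}

photons <- as.numeric(get_arg("--photons", "1e5"))
seed <- as.integer(get_arg("--seed", "1"))
lib <- chromophore_library()

if (cmd == "train") {
  out <- get_arg("--out", "model.json")
  records <- simulate_training_set(build_training_grid(),
                                   transport_config(photons, seed), lib)
  model <- fit_regression(records)
  print(model)
  write_hb_model(model, out)
  message("wrote ", out)
} else if (cmd == "estimate") {
  model <- read_hb_model(get_arg("--model", "model.json"))
  stack <- read_stack(get_arg("--stack"))
  out <- get_arg("--out", "maps")
  maps <- estimate_maps(stack, model)
  print(maps)
  write_maps(maps, out)
  message("wrote maps under ", out)
} else if (cmd == "timecourse") {
  # one parameter_maps set per prefix (time point), sorted by prefix name;
  # each single-channel image in --rois is one ROI mask (nonzero = inside)
  maps_dir <- get_arg("--maps-dir")
  prefixes <- sort(unique(sub("_cth\\.tif$", "",
                              list.files(maps_dir, "_cth\\.tif$"))))
  if (length(prefixes) < 2) stop("need at least two time points in ", maps_dir)
  maps <- lapply(prefixes, function(p) read_maps(maps_dir, p))
  roi_files <- list.files(get_arg("--rois"), "\\.tif$", full.names = TRUE)
  rois <- lapply(roi_files, function(f) {
    m <- tiff::readTIFF(f)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m > 0.5
  })
  names(rois) <- tools::file_path_sans_ext(basename(roi_files))
  baseline <- as.integer(get_arg("--baseline", "1"))
  tc <- relative_change(maps, rois, baseline_index = baseline)
  out <- get_arg("--out", "tc.csv")
  write_timecourse(tc, out)
  message("wrote ", out)
} else if (cmd == "imc") {
  meas <- utils::read.csv(get_arg("--measurements"))
  threshold <- as.numeric(get_arg("--threshold", "0.005"))
  cfg <- transport_config(photons, seed)
  res <- do.call(rbind, lapply(seq_len(nrow(meas)), function(i) {
    inv <- invert_slab(as.list(meas[i, ]), cfg, threshold = threshold)
    cbind(meas[i, c("phantom", "wavelength")], inv)
  }))
  # per-phantom summary: Cth from mua(585), (a, b) from the musp spectrum
  summ <- do.call(rbind, lapply(split(res, res$phantom), function(d) {
    ab <- b_from_musp(d$musp, d$wavelength)
    data.frame(phantom = d$phantom[1],
               cth = cth_from_mua(d$mua[d$wavelength == 585], lib),
               a = ab$a, b = ab$b)
  }))
  out <- get_arg("--out", "props.csv")
  utils::write.csv(res, out, row.names = FALSE)
  utils::write.csv(summ, sub("\\.csv$", "_summary.csv", out), row.names = FALSE)
  message("wrote ", out)
} else if (cmd == "simulate") {
  dim <- as.integer(get_arg("--dim", "64"))
  out <- get_arg("--out", "scene")
  sc <- lesion_scene(skin_parameters(cm = 1, cth = 0.4, a = 6.3e9, b = 3.0),
                     skin_parameters(cm = 1, cth = 0.8, a = 6.3e9, b = 2.9),
                     dim = dim, seed = seed)
  gen <- generate_image_stack(sc, transport_config(photons, seed), lib)
  write_stack(gen$stack, out)
  utils::write.csv(tibble::as_tibble(gen$truth),
                   file.path(out, "truth.csv"), row.names = FALSE)
  message("wrote scene under ", out)
} else {
  stop("unknown subcommand: ", cmd)
}
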