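make_stack <- function(is_fun, iw_fun = function(nm) matrix(1, 4, 5)) {
  lams <- as.character(isosbestic_wavelengths())
  reflectance_stack(setNames(lapply(lams, is_fun), lams),
                    setNames(lapply(lams, iw_fun), lams))
}

test_that("normalization divides out the white reference and guards zeros", {
  iw <- matrix(2, 4, 5)
  st <- make_stack(function(nm) iw, function(nm) iw)
  nr <- normalize_reflectance(st)
  expect_true(all(sapply(nr$R, function(r) all(r == 1))))

  st2 <- make_stack(function(nm) 0.5 * iw, function(nm) iw)
  nr2 <- normalize_reflectance(st2)
  expect_true(all(sapply(nr2$R, function(r) all(r == 0.5))))

  # a zero white-reference pixel is invalid, not infinite
  iw0 <- iw; iw0[2, 3] <- 0
  st3 <- make_stack(function(nm) iw, function(nm) iw0)
  nr3 <- normalize_reflectance(st3)
  expect_false(nr3$valid[2, 3])
  expect_true(is.na(nr3$R[["420"]][2, 3]))
  expect_true(all(nr3$valid[-(2 + (3 - 1) * 4)]))
})

test_that("stack construction enforces band names and dimensions", {
  img <- matrix(0.5, 4, 5)
  expect_error(reflectance_stack(list(`420` = img), list(`420` = 1)), "named")
  bad <- list(`420` = img, `450` = img, `500` = img, `585` = matrix(0.5, 3, 5))
  white <- list(`420` = 1, `450` = 1, `500` = 1, `585` = 1)
  expect_error(reflectance_stack(bad, white), "dimensions")
})

test_that("absorbance follows the decade rule", {
  expect_equal(absorbance(1), 0)
  expect_equal(absorbance(0.1), 1)
  expect_equal(absorbance(0.01), 2)
  expect_error(absorbance(c(0.5, 0)), "non-positive")
  expect_error(absorbance(-0.1), "non-positive")
})

test_that("estimate_maps applies the fitted formulas pixelwise", {
  m <- small_model()
  recs <- small_records()
  # build a stack whose reflectances are exactly one training record's:
  # the map estimate must equal the model's fitted value for that record
  rec <- recs[17, ]
  st <- make_stack(function(nm) matrix(rec[[paste0("R", nm)]], 4, 5))
  maps <- estimate_maps(st, m)
  fitted <- predict(m, rec)
  expect_equal(maps$cth_map[1, 1], fitted$cth_est, tolerance = 1e-12)
  expect_equal(maps$b_map[1, 1], fitted$b_est, tolerance = 1e-12)
  # identical absorbances give identical estimates everywhere
  expect_equal(length(unique(as.vector(maps$b_map))), 1)
})

test_that("all-invalid stacks yield fully masked maps without error", {
  st <- make_stack(function(nm) matrix(0.5, 4, 5),
                   function(nm) matrix(0, 4, 5))
  maps <- estimate_maps(st, small_model())
  expect_false(any(maps$valid_mask))
  expect_true(all(is.na(maps$cth_map)))
})

test_that("estimates are invariant to a global gain on sample and reference", {
  m <- small_model()
  set.seed(8)
  base <- matrix(runif(20, 0.2, 0.8), 4, 5)
  st1 <- make_stack(function(nm) base)
  st2 <- make_stack(function(nm) 7.3 * base, function(nm) matrix(7.3, 4, 5))
  m1 <- estimate_maps(st1, m)
  m2 <- estimate_maps(st2, m)
  expect_equal(m1$cth_map, m2$cth_map, tolerance = 1e-12)
  expect_equal(m1$b_map, m2$b_map, tolerance = 1e-12)
})

test_that("grid-hash mismatch between model and stack is refused", {
  st <- make_stack(function(nm) matrix(0.5, 4, 5))
  expect_error(estimate_maps(st, small_model(), expected_hash = "nope"),
               "grid_hash")
})

test_that("relative change reproduces the delta formulas", {
  mk_maps <- function(cth, b) {
    structure(list(cth_map = matrix(cth, 4, 4), b_map = matrix(b, 4, 4),
                   valid_mask = matrix(TRUE, 4, 4), dims = c(4, 4),
                   timestamp = NA_character_), class = "parameter_maps")
  }
  roi <- list(all = matrix(TRUE, 4, 4))
  series <- list(mk_maps(0.4, 3.0), mk_maps(0.4, 3.0),
                 mk_maps(0.8, 2.7), mk_maps(0.4, 3.0))
  tc <- relative_change(series, roi, times = 0:3)
  expect_equal(tc$delta_cth_pct[tc$time == 0], 0)
  expect_equal(tc$delta_b_pct[tc$time == 0], 0)
  expect_equal(tc$delta_cth_pct[tc$time == 1], 0)
  expect_equal(tc$delta_cth_pct[tc$time == 2], 100)          # doubling
  expect_equal(tc$delta_b_pct[tc$time == 2], -10)            # 0.9 * baseline
  expect_equal(tc$delta_cth_pct[tc$time == 3], 0)
})

test_that("relative change flags a zero baseline", {
  mk <- function(cth) structure(
    list(cth_map = matrix(cth, 2, 2), b_map = matrix(3, 2, 2),
         valid_mask = matrix(TRUE, 2, 2), dims = c(2, 2),
         timestamp = NA_character_), class = "parameter_maps")
  expect_error(relative_change(list(mk(0), mk(1)), list(matrix(TRUE, 2, 2))),
               "baseline")
})

test_that("maps flatten to a tidy tibble and render", {
  m <- small_model()
  st <- make_stack(function(nm) matrix(0.4, 4, 5))
  maps <- estimate_maps(st, m)
  tb <- tibble::as_tibble(maps)
  expect_equal(nrow(tb), 20)
  expect_named(tb, c("row", "col", "cth", "b", "valid"))
  p <- ggplot2::autoplot(maps)
  expect_s3_class(p, "ggplot")
})

test_that("stacks and maps round-trip through TIFF + YAML", {
  dir <- tempfile()
  set.seed(2)
  st <- make_stack(function(nm) matrix(runif(20, 0.1, 0.9), 4, 5))
  side <- write_stack(st, dir)
  st2 <- read_stack(side)
  expect_equal(st2$images[["500"]], st$images[["500"]], tolerance = 1e-6)
  maps <- estimate_maps(st, small_model())
  paths <- write_maps(maps, dir)
  expect_true(all(file.exists(paths)))
  back <- read_maps(dir)
  expect_equal(back$cth_map[maps$valid_mask], maps$cth_map[maps$valid_mask],
               tolerance = 1e-4)
  expect_equal(back$b_map[maps$valid_mask], maps$b_map[maps$valid_mask],
               tolerance = 1e-4)
  expect_equal(back$valid_mask, maps$valid_mask)
})
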