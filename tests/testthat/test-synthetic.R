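quick_cfg <- function(seed = 1) transport_config(5e3, seed = seed)

test_that("phantom sets are deterministic and span the requested ranges", {
  p1 <- generate_phantom_set(n = 4, cfg = quick_cfg(), lib = lib_fx, seed = 3)
  p2 <- generate_phantom_set(n = 4, cfg = quick_cfg(), lib = lib_fx, seed = 3)
  expect_identical(p1$truth, p2$truth)
  expect_identical(p1$reflectance, p2$reflectance)
  expect_true(all(p1$truth$cth >= 0.3 & p1$truth$cth <= 0.9))
  expect_true(all(p1$truth$b >= 2.92 & p1$truth$b <= 3.08))
  expect_equal(nrow(p1$reflectance), 16)
  expect_equal(nrow(p1$slab), 16)
  # slab records: R + T < 1 and positive
  expect_true(all(p1$slab$reflectance + p1$slab$transmittance < 1))
})

test_that("degenerate ranges collapse phantoms to identical truth", {
  pt <- list(cm = c(1, 1), cth = c(0.5, 0.5), a = c(6.3e9, 6.3e9),
             b = c(3, 3))
  p <- generate_phantom_set(n = 2, ranges = pt, cfg = quick_cfg(),
                            lib = lib_fx, seed = 1, slab = FALSE)
  expect_equal(p$truth$cth[1], p$truth$cth[2])
  expect_equal(p$truth$b[1], p$truth$b[2])
})

test_that("ranges outside the training grid are flagged as extrapolation", {
  expect_warning(
    generate_phantom_set(n = 2, ranges = list(cm = c(1, 1), cth = c(0.1, 1.5),
                                              a = c(6e9, 6e9), b = c(3, 3)),
                         cfg = quick_cfg(), lib = lib_fx, slab = FALSE),
    "extrapolate"
  )
})

test_that("uniform scenes render to constant noiseless stacks that re-estimate", {
  sc <- uniform_scene(skin_parameters(cm = 5, cth = 0.6, a = 6.3e9, b = 3.0),
                      dim = 8, noise_sigma = 0, seed = 11)
  out <- generate_image_stack(sc, transport_config(3e4, seed = 13), lib_fx)
  img <- out$stack$images[["585"]]
  expect_equal(length(unique(as.vector(img))), 1)
  maps <- estimate_maps(out$stack, default_model())
  expect_lt(abs(mean(maps$cth_map) - 0.6), 0.1)
  expect_lt(abs(mean(maps$b_map) - 3.0), 0.05)
  # truth maps come from the generator, not the estimator
  expect_equal(out$truth$cth_map[1, 1], 0.6)
})

test_that("regenerating a noiseless scene with the same seed is bit-identical", {
  sc <- uniform_scene(skin_parameters(), dim = 6, noise_sigma = 0, seed = 7)
  s1 <- generate_image_stack(sc, quick_cfg(2), lib_fx)
  s2 <- generate_image_stack(sc, quick_cfg(2), lib_fx)
  expect_identical(s1$stack$images, s2$stack$images)
})

test_that("quantization limits the number of distinct pixel levels", {
  sc <- uniform_scene(skin_parameters(), dim = 16, noise_sigma = 0.05,
                      quantize_bits = 8, seed = 5)
  out <- generate_image_stack(sc, quick_cfg(3), lib_fx)
  for (img in out$stack$images) {
    expect_lte(length(unique(as.vector(img))), 256)
  }
})

test_that("a vascularized lesion shows the right contrast sign in both maps", {
  bg <- skin_parameters(cm = 1, cth = 0.4, a = 6.3e9, b = 3.00)
  tum <- skin_parameters(cm = 1, cth = 0.8, a = 6.3e9, b = 2.92)
  sc <- lesion_scene(bg, tum, dim = 16, radius = 4, noise_sigma = 0.01,
                     seed = 19)
  out <- generate_image_stack(sc, transport_config(2e4, seed = 23), lib_fx)
  maps <- estimate_maps(out$stack, default_model())
  inside <- sc$class_map == 2
  expect_gt(mean(maps$cth_map[inside]), mean(maps$cth_map[!inside]))
  expect_lt(mean(maps$b_map[inside]), mean(maps$b_map[!inside]))
})

test_that("time-course schedules are recovered by the estimation pipeline", {
  sc <- uniform_scene(skin_parameters(cm = 2, cth = 0.5, a = 6.3e9, b = 3.0),
                      dim = 8, noise_sigma = 0.01, seed = 29)
  schedule <- tibble::tibble(week = c(0, 3, 6),
                             cth_mult = c(1, 1, 1.5),
                             b_mult = c(1, 0.97, 0.97))
  tcgen <- generate_timecourse(sc, schedule, transport_config(5e4, seed = 31),
                               lib_fx)
  m <- default_model()
  maps <- lapply(tcgen$stacks, estimate_maps, model = m)
  tc <- relative_change(maps, list(all = matrix(TRUE, 8, 8)),
                        times = tcgen$weeks)
  expect_equal(tc$delta_cth_pct[tc$time == 0], 0)
  # +50% hemoglobin at week 6: recovered as a clearly positive excursion,
  # compressed by the curvature of the linear formulas at high Cth (the
  # regression under-reads large excursions; see the methods vignette)
  expect_gt(tc$delta_cth_pct[tc$time == 6], 15)
  expect_lt(tc$delta_cth_pct[tc$time == 6], 60)
  # -3% scattering power from week 3 onward
  expect_lt(abs(tc$delta_b_pct[tc$time == 3] - (-3)), 2.5)
  expect_lt(abs(tc$delta_b_pct[tc$time == 6] - (-3)), 2.5)
  expect_lt(abs(tc$delta_cth_pct[tc$time == 3] - 0), 15)
})

test_that("schedules without a unit baseline are refused", {
  sc <- uniform_scene(skin_parameters(), dim = 4, seed = 1)
  expect_error(
    generate_timecourse(sc, tibble::tibble(week = c(0, 1),
                                           cth_mult = c(1.2, 1),
                                           b_mult = c(1, 1)),
                        quick_cfg(), lib_fx),
    "week 0"
  )
})

test_that("end-to-end recovery correlates strongly over random scenes", {
  m <- default_model()
  set.seed(99)
  n <- 50
  truth <- tibble::tibble(
    cm = runif(n, 1, 10), cth = runif(n, 0.25, 0.95),
    a = runif(n, 5.4e9, 7.2e9), b = runif(n, 2.91, 3.09)
  )
  est <- purrr::map_dfr(seq_len(n), function(i) {
    st <- build_skin_model(truth[i, ], lib = lib_fx)
    sim <- simulate_stack_at_wavelengths(st,
                                         cfg = transport_config(2e4,
                                                                seed = 7000 + i))
    R <- sim$diffuse_reflectance * (1 + 0.01 * rnorm(4))
    A <- setNames(as.list(-log10(R)), paste0("A", sim$wavelength))
    predict(m, A)
  })
  # the b correlation is capped near 0.9 by the linear formulas' residual
  # at the edges of the (a, b) grid even before noise (methods vignette);
  # under per-scene 1% noise the attainable level is asserted here
  expect_gt(cor(truth$cth, est$cth_est), 0.88)
  expect_gt(cor(truth$b, est$b_est), 0.80)
})
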