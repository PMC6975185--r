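# shared fixtures: chromophore library, cached trained models, and a naive
# reference random walker used as an independent transport oracle

lib_fx <- chromophore_library()

.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# coarse 81-state grid spanning the same ranges as the default design;
# used where full-grid accuracy is not the point
small_records <- function() fixture("small_records", {
  grid <- build_training_grid(a_values = c(5.3e9, 6.3e9, 7.3e9),
                              b_values = c(2.90, 3.00, 3.10),
                              cm_values = c(1, 5, 10),
                              cth_values = c(0.2, 0.6, 1.0))
  simulate_training_set(grid, transport_config(2e4, seed = 101), lib_fx)
})
small_model <- function() fixture("small_model", fit_regression(small_records()))

# the canonical 1250-state design, photon count chosen so the whole test run
# stays desk-scale
default_records <- function() fixture("default_records", {
  simulate_training_set(build_training_grid(),
                        transport_config(1e5, seed = 2024), lib_fx)
})
default_model <- function() fixture("default_model",
                                    fit_regression(default_records()))

# Naive analog random walker, deliberately unoptimized and independent of
# the compiled kernel: matched-index single layer, analog absorption
# (photon dies with probability mua/mut at each collision), isotropic or HG
# scattering. Returns the escaping-top fraction and its standard error.
naive_reference_walker <- function(mua, mus, g, d_cm, n_photons, seed) {
  set.seed(seed)
  mut <- mua + mus
  hits <- 0
  for (i in seq_len(n_photons)) {
    z <- 0; uz <- 1; ux <- 0; uy <- 0
    repeat {
      s <- -log(runif(1)) / mut
      z <- z + uz * s
      if (z < 0) { hits <- hits + 1; break }
      if (z > d_cm) break
      if (runif(1) < mua / mut) break  # absorbed
      if (abs(g) < 1e-9) {
        ct <- 2 * runif(1) - 1
      } else {
        tmp <- (1 - g^2) / (1 - g + 2 * g * runif(1))
        ct <- (1 + g^2 - tmp^2) / (2 * g)
      }
      st <- sqrt(max(0, 1 - ct^2))
      phi <- 2 * pi * runif(1)
      if (abs(uz) > 0.99999) {
        ux <- st * cos(phi); uy <- st * sin(phi); uz <- ct * sign(uz)
      } else {
        den <- sqrt(1 - uz^2)
        ux2 <- st * (ux * uz * cos(phi) - uy * sin(phi)) / den + ux * ct
        uy2 <- st * (uy * uz * cos(phi) + ux * sin(phi)) / den + uy * ct
        uz2 <- -den * st * cos(phi) + uz * ct
        ux <- ux2; uy <- uy2; uz <- uz2
      }
    }
  }
  p <- hits / n_photons
  list(reflectance = p, se = sqrt(p * (1 - p) / n_photons))
}
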