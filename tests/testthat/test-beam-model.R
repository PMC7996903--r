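test_that("parameter validation catches ill-formed beam models", {
  expect_error(beam_model_params(fractions = c(thermal = 0.5,
                                               epithermal = 0.4,
                                               fast = 0.2)),
               "sum to 1")
  expect_error(beam_model_params(mean_directionality = 0))
  expect_error(beam_model_params(mean_directionality = 1.2))
  expect_error(beam_model_params(total_flux = -1))
})

test_that("generated spectra reproduce requested band fractions", {
  # property over several mixtures and grid sizes (>= 50 bins)
  set.seed(42)
  for (i in 1:5) {
    f <- runif(3)
    f <- f / sum(f)
    names(f) <- c("thermal", "epithermal", "fast")
    for (nb in c(50L, 100L, 173L)) {
      g <- make_energy_grid(1e-3, 1e7, nb)
      sp <- generate_beam_spectrum(g, beam_model_params(fractions = f))
      b <- band_integrals(sp)
      tot <- sum(sp$flux_per_bin)
      got <- c(b$phi_th, b$phi_epi, b$phi_fast) / tot
      expect_equal(got, unname(f), tolerance = 0.01)
      expect_equal(sum(sp$flux_per_bin),
                   beam_model_params(fractions = f)$total_flux)
    }
  }
})

test_that("spectral mode lies in the 1-10 keV band for a well-moderated beam", {
  f <- c(thermal = 0.009, epithermal = 0.99, fast = 0.001)
  sp <- default_spectrum(beam_model_params(
    fractions = f / sum(f), epithermal_peak_energy = 1e3))
  mode_e <- sp$grid$mids[which.max(sp$flux_per_bin)]
  expect_gte(mode_e, 1e3)
  expect_lte(mode_e, 1e4)
})

test_that("a pure-thermal mixture puts all flux below 0.5 eV", {
  sp <- default_spectrum(beam_model_params(
    fractions = c(thermal = 1, epithermal = 0, fast = 0)))
  hot <- sp$grid$mids >= 0.5
  expect_equal(sum(sp$flux_per_bin[hot]), 0)
  expect_gt(sum(sp$flux_per_bin[!hot]), 0)
})

test_that("band fractions are seed-invariant even with bin noise on", {
  p <- beam_model_params()
  b1 <- band_integrals(generate_beam_spectrum(default_grid, p,
                                              seed = 7, noise_sd = 0.3))
  b2 <- band_integrals(generate_beam_spectrum(default_grid, p,
                                              seed = 1234,
                                              noise_sd = 0.3))
  expect_equal(b1$phi_th, b2$phi_th)
  expect_equal(b1$phi_epi, b2$phi_epi)
  expect_equal(b1$phi_fast, b2$phi_fast)
})

test_that("current is the directed fraction of the flux in every bin", {
  p <- beam_model_params(mean_directionality = 0.6)
  sp <- default_spectrum(p)
  expect_equal(sp$current_per_bin, 0.6 * sp$flux_per_bin)
  expect_true(all(sp$current_per_bin <= sp$flux_per_bin + 1e-12))
})

test_that("radial profile is normalized on axis and flat within the ripple in-beam", {
  p <- beam_model_params()  # port 6 cm, ripple 0.2
  expect_equal(radial_flux_profile(p, 0), 1)
  inside <- radial_flux_profile(p, seq(0, 6, by = 0.1))
  expect_true(all(inside > 0 & inside <= 1))
  expect_lte(max(inside) / min(inside), 1 + p$in_beam_ripple + 1e-12)
  expect_gte(radial_flux_profile(p, 6) / radial_flux_profile(p, 0), 0.8)
})

test_that("radial profile decreases strictly beyond the port and rejects negative radii", {
  p <- beam_model_params()
  out <- radial_flux_profile(p, seq(6, 20, by = 0.5))
  expect_true(all(diff(out) < 0))
  expect_lt(radial_flux_profile(p, 12), radial_flux_profile(p, 6))
  expect_error(radial_flux_profile(p, -1))
})

test_that("spectrum files round-trip through the tabular text format", {
  sp <- default_spectrum()
  f <- withr::local_tempfile(fileext = ".csv")
  write_beam_spectrum(sp, f)
  back <- read_beam_spectrum(f)
  expect_equal(back$flux_per_bin, sp$flux_per_bin, tolerance = 1e-6)
  expect_equal(back$current_per_bin, sp$current_per_bin,
               tolerance = 1e-6)
  expect_equal(back$gamma_dose_rate, sp$gamma_dose_rate)
  expect_equal(back$fast_dose_rate, sp$fast_dose_rate)
  expect_equal(back$port_radius, sp$port_radius)
  expect_equal(back$grid$edges, sp$grid$edges, tolerance = 1e-6)
})
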