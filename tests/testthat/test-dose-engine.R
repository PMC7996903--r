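test_that("absorbed dose assembles rate x time with boron picking up ppm", {
  cmp <- dose_components(boron_per_ppm = 0.01, thermal_n = 0.002,
                         fast_n = 0.001, gamma = 0.05)
  a0 <- absorbed_dose(cmp, table3_tumor, 0)
  expect_equal(unlist(a0), c(boron = 0, thermal_n = 0, fast_n = 0,
                             gamma = 0, total = 0))
  a <- absorbed_dose(dose_components(boron_per_ppm = 0.01),
                     table3_tumor, 10)
  expect_equal(a$boron, 5.25)
  expect_error(absorbed_dose(cmp, table3_tumor, -1), "nonnegative")

  # brute-force per-term oracle over random rates/times
  set.seed(99)
  for (i in 1:10) {
    r <- runif(4, 0, 0.1)
    t <- runif(1, 0, 60)
    cmp <- dose_components(r[1], r[2], r[3], r[4])
    a <- absorbed_dose(cmp, table3_kidney, t)
    expect_equal(a$boron, r[1] * 75 * t)
    expect_equal(a$thermal_n, r[2] * t)
    expect_equal(a$fast_n, r[3] * t)
    expect_equal(a$gamma, r[4] * t)
    expect_equal(a$total, a$boron + a$thermal_n + a$fast_n + a$gamma)
  }
})

test_that("fixed-RBE weighting matches hand-computed unit cases", {
  # tumor factors (1, 2.2, 5.3): one Gy of each radiation type
  a <- list(boron = 1, thermal_n = 0.5, fast_n = 0.5, gamma = 1)
  expect_equal(weighted_dose_fixed_rbe(a, table3_tumor),
               1 * 1 + 2.2 * 1 + 5.3 * 1)  # 8.5 Gy-Eq
  # skin factors (1, 2.5, 2.5), photon-only dose
  expect_equal(weighted_dose_fixed_rbe(
    list(boron = 0, thermal_n = 0, fast_n = 0, gamma = 2),
    table3_skin), 2)
  # zero in, zero out
  expect_equal(weighted_dose_fixed_rbe(
    list(boron = 0, thermal_n = 0, fast_n = 0, gamma = 0),
    table3_tumor), 0)
})

test_that("all-factors-one weighting degenerates to the absorbed total", {
  unit <- tissue_composition("unit", boron_ppm = 15, rbe_gamma = 1,
                             rbe_neutron = 1, cbe_boron = 1)
  set.seed(7)
  for (i in 1:10) {
    a <- as.list(runif(4))
    names(a) <- c("boron", "thermal_n", "fast_n", "gamma")
    expect_equal(weighted_dose_fixed_rbe(a, unit),
                 sum(unlist(a)))
  }
})

test_that("the neutron weighting curve is near-continuous and peaks near 1 MeV", {
  # the standard three-piece curve's branches meet only to ~0.1% at
  # 1 and 50 MeV; check the jumps stay at that level
  expect_equal(neutron_wr(1e6 - 1), neutron_wr(1e6 + 1),
               tolerance = 1e-3)
  expect_equal(neutron_wr(50e6 - 1), neutron_wr(50e6 + 1),
               tolerance = 1e-3)
  expect_equal(neutron_wr(1e6), 5 + 17 * exp(-log(2)^2 / 6))
  # thermal neutrons carry a small weight, ~2.5
  expect_lt(neutron_wr(0.025), 3)
  expect_gt(neutron_wr(0.025), 2.4)
  expect_gt(neutron_wr(1e6), neutron_wr(1e3))
  expect_error(neutron_wr(0))
})

test_that("equivalent dose weights photons by 1, boron by 20, neutrons by wR(E)", {
  expect_equal(equivalent_dose_icrp(
    list(boron = 0, thermal_n = 0, fast_n = 0, gamma = 1)), 1)
  expect_equal(equivalent_dose_icrp(
    list(boron = 0.5, thermal_n = 0, fast_n = 0, gamma = 0)), 10)
  # monoenergetic 1 MeV neutron dose of 1 Gy
  expect_equal(equivalent_dose_icrp(
    list(boron = 0, thermal_n = 0, fast_n = 1, gamma = 0),
    neutron_energy_ev = 1e6), neutron_wr(1e6))
  # energy-resolved neutron dose
  expect_equal(equivalent_dose_icrp(
    list(boron = 0, thermal_n = 0.2, fast_n = 0.3, gamma = 0.1),
    neutron_energy_ev = c(0.025, 1e6),
    neutron_dose_gy = c(0.2, 0.3)),
    0.1 + 0.2 * neutron_wr(0.025) + 0.3 * neutron_wr(1e6))
  # neutron dose without energy information is an error
  expect_error(equivalent_dose_icrp(
    list(boron = 0, thermal_n = 1, fast_n = 0, gamma = 0)),
    "energy")
})

test_that("equivalent dose dominates absorbed total when all weights >= 1", {
  set.seed(12)
  for (i in 1:10) {
    a <- as.list(runif(4))
    names(a) <- c("boron", "thermal_n", "fast_n", "gamma")
    a$total <- sum(unlist(a))
    expect_gte(equivalent_dose_icrp(a, neutron_energy_ev = 1e4),
               a$total)
  }
})

test_that("component percentages normalize to 100 and match an oracle", {
  p <- component_percentages(list(boron = 62, thermal_n = 9,
                                  fast_n = 6, gamma = 23))
  expect_equal(unname(p), c(62, 9, 6, 23))
  expect_equal(unname(component_percentages(
    list(boron = 0, thermal_n = 0, fast_n = 3.2, gamma = 0))),
    c(0, 0, 100, 0))
  set.seed(3)
  for (i in 1:10) {
    v <- runif(4)
    p <- component_percentages(list(boron = v[1], thermal_n = v[2],
                                    fast_n = v[3], gamma = v[4]))
    expect_equal(unname(p), 100 * v / sum(v))
    expect_equal(sum(p), 100)
  }
  expect_error(component_percentages(list(boron = 0, thermal_n = 0,
                                          fast_n = 0, gamma = 0)),
               "zero")
})

test_that("tissue tables round-trip and unlisted organs get default factors", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_tissue_table(default_tissue_table(), f)
  back <- read_tissue_table(f)
  expect_equal(back$boron_ppm, default_tissue_table()$boron_ppm)
  # bundled factor table mirrors the defaults for its tissues
  bundled <- read_tissue_table(system.file("extdata",
                                           "rbe_cbe_factors.csv",
                                           package = "bnctbeams"))
  expect_equal(bundled$cbe_boron[bundled$tissue == "tumor"], 5.3)
  # plural organ names resolve to singular tissue rows
  k <- bnctbeams:::lookup_tissue("Kidneys", default_tissue_table())
  expect_equal(k$boron_ppm, 75)
  # unlisted organ falls back to generic normal tissue
  g <- bnctbeams:::lookup_tissue("Pharynx", default_tissue_table())
  expect_equal(c(g$rbe_neutron, g$cbe_boron, g$boron_ppm),
               c(3.2, 1.3, 15))
  expect_error(bnctbeams:::lookup_tissue("Pharynx",
                                         default_tissue_table(),
                                         default_ok = FALSE),
               "no tissue factors")
})
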